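group,qale,opp_share,pop_share
IMD1,63.210000,0.260000,0.200000
IMD2,66.157500,0.230000,0.200000
IMD3,69.105000,0.200000,0.200000
IMD4,72.052500,0.170000,0.200000
IMD5,75.000000,0.140000,0.200000
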