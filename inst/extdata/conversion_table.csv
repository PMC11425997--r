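currency,price_year,multiplier_to_usd2023,provenance
USD,2023,1,identity
GBP,2015,1.69102708333333,back_solved
AUD,2019,0.751558411214954,back_solved
EUR,2016,1.74443331166667,back_solved
EUR,2020,1.3425332015,back_solved
USD,2021,1.04184002873333,back_solved
AUD,2020,0.73982,back_solved
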