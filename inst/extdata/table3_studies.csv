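"study_id","strategy_type","outcome_measure","delta_cost_usd2023","delta_effect","cost_low","cost_high","effect_low","effect_high","wtp_usd2023","perspective"
"Kerr","cascade","QALY","4702.79","0.47999999999999998","","","","","50730.812500000007","healthcare"
"Ademi40","cascade","QALY","-852.30999999999995","1.0700000000000001","","","","","21043.63551401869","healthcare"
"Ademi42","cascade","QALY","84620.279999999999","29.07","","","","","4900.0096319229442","healthcare"
"Lazaro","cascade","QALY","39591894.469999999","767","","","","","52332.999308996084","healthcare"
"Ademi32","cascade","QALY","31369.18","2.5299999999999998","","","","","26850.664031620552","healthcare"
"Ademi40","cascade","LYG","-852.30999999999995","0.96999999999999997","","","","","21042.9793814433","healthcare"
"Ademi42","cascade","LYG","84620.279999999999","24.949999999999999","","","","","4899.9711422845694","healthcare"
"Oliva","cascade","LYG","8922.6900000000005","1.3400000000000001","","","","","19425.888059701494","healthcare"
"Wonderling","cascade","LYG","11433.059999999999","0.90000000000000002","","","","","35524.511111111111","healthcare"
"Ademi32","cascade","LYG","31369.18","2.2799999999999998","","","","","26850.956140350878","healthcare"
"Kerr","cascade","adverse_events_averted","4702.79","104","","","","","50730.997980769229","healthcare"
"Ademi40","cascade","adverse_events_averted","-852.30999999999995","24.199999999999999","","","","","21043.995454545457","healthcare"
"Lazaro","cascade","adverse_events_averted","39591894.469999999","847","","","","","52332.999374262101","healthcare"
"Kerr","cascade","deaths_averted","4702.79","16","","","","","50730.986875000002","healthcare"
"Marks","cascade","deaths_averted","101486932.5","560","","","","","65572.999107142852","healthcare"
"Ademi40","cascade","deaths_averted","-852.30999999999995","7.5499999999999998","","","","","21044.064900662252","healthcare"
"Lazaro","cascade","deaths_averted","39591894.469999999","203","","","","","52333.002315270933","healthcare"
"Marquina","universal","QALY","1061544599.77","51790","","","","","36990.999995558988","healthcare"
"Spencer","universal","QALY","20836899.420000002","97.5","","","","","156276.00430769232","healthcare"
"Marquina","universal","LYG","1061544599.77","33488","","","","","36990.999993131867","healthcare"
"Spencer","universal","LYG","20836899.420000002","61.5","","","","","156276.00682926833","healthcare"
"Marks","universal","deaths_averted","13500753.09","11.699999999999999","","","","","65572.999145299138","healthcare"
"Marquina","universal","deaths_averted","1061544599.77","1279","","","","","36990.999820171994","healthcare"
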