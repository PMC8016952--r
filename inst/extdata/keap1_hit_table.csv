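compound_id,primary_inhibition_pct,counter_inhibition_pct,rank_ti,rank_pi,nearest_known_similarity
hit01,85.5,65.2,129,44,0.228
hit02,74.3,NI,1320,419,0.253
hit03,47.0,4.9,2604,426,0.241
hit04,29.9,NI,905,775,0.262
hit05,29.2,NI,19,70,0.256
hit06,27.1,NI,6830,326,0.155
hit07,22.1,NI,1253,242,0.175
hit08,22.1,5.1,44,51,0.258
hit09,18.5,NI,1578,3366,0.141
hit10,18.3,NI,1475,256,0.164
hit11,18.2,1.0,1868,525,0.233
hit12,18.1,6.4,1365,3382,0.143
hit13,17.7,NI,10755,527,0.151
hit14,17.2,NI,497,274,0.170
hit15,16.8,NI,898,1946,0.234
hit16,15.2,NI,3197,5548,0.138
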