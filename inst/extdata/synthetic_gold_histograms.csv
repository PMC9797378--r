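histogram_id,f1,f2,f3,f4,f5,gold
h01,0.9,0.07,0.02,0.007,0.003,10
h02,0.1,0.2,0.4,0.2,0.1,10
h03,0.2,0.2,0.2,0.2,0.2,10
h04,0.05,0.1,0.7,0.1,0.05,10
h05,0.5,0.3,0.1,0.06,0.04,10
h06,0.03,0.07,0.2,0.3,0.4,10
h07,0.1,0,0,0,0.9,27
h08,0.85,0,0.15,0,0,35.5
h09,0.2,0,0,0,0.8,44
h10,0.05,0,0.25,0,0.7,52.5
h11,0.3,0,0,0,0.7,61
h12,0,0.35,0,0.65,0,69.5
h13,0.4,0,0.05,0.05,0.5,78
h14,0.45,0,0,0,0.55,86.5
h15,0.5,0,0,0,0.5,95
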