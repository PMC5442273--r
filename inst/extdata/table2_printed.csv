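index,mda,donors_protons,risk
1,6.7000,38.5000,9.3440
2,6.6440,38.6975,9.1448
3,6.5880,38.8950,8.9813
4,6.5320,39.0925,8.8406
5,6.4760,39.2900,8.7140
44,4.2920,46.9925,6.2051
45,4.2360,47.1900,6.1213
46,4.1800,47.3875,6.0331
47,4.1240,47.5850,5.9395
48,4.0680,47.7825,5.8392
97,1.3240,57.4600,2.2594
98,1.2680,57.6575,2.1276
99,1.2120,57.8550,1.9800
100,1.1560,58.0525,1.8076
101,1.1000,58.2500,1.6560
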