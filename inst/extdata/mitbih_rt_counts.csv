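record,total,fn_r,fn_t,fp_r,fp_t,der_r,der_t,se_r,se_t,acc_r,acc_t
200,2601,1,1,6,8,0.27,0.35,99.96,99.96,99.73,99.65
201,1963,0,1,2,2,0.10,0.15,100.00,99.95,99.90,99.85
202,2136,1,2,7,9,0.38,0.52,99.95,99.91,99.63,99.49
203,2980,11,12,5,6,0.54,0.61,99.63,99.60,99.46,99.40
205,2656,1,1,0,1,0.04,0.08,99.96,99.96,99.96,99.92
207,1862,0,1,1,1,0.05,0.11,100.00,99.95,99.95,99.89
208,2955,8,9,5,5,0.44,0.48,99.73,99.69,99.56,99.53
209,3005,1,1,0,1,0.03,0.07,99.97,99.97,99.97,99.93
210,2650,6,7,3,4,0.34,0.42,99.77,99.74,99.66,99.58
215,3363,0,1,0,0,0.00,0.03,100.00,99.97,100.00,99.97
217,2208,2,2,2,3,0.18,0.23,99.91,99.91,99.82,99.77
219,2154,1,0,2,2,0.14,0.09,99.95,100.00,99.86,99.91
220,2048,1,1,1,1,0.10,0.10,99.95,99.95,99.90,99.90
223,2605,2,1,0,0,0.08,0.04,99.92,99.96,99.92,99.96
228,2053,7,7,7,8,0.69,0.74,99.66,99.66,99.32,99.27
230,2256,1,1,3,3,0.18,0.18,99.96,99.96,99.82,99.82
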