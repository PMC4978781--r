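item_id,var_a,var_b,var_c,cov_ab,cov_ac,cov_bc
1,0.023,0.001,0.002,0.001,0.006,0.001
2,0.020,0.001,0.001,0.001,0.003,0.001
3,0.015,0.001,0.000,0.001,0.002,0.000
4,0.015,0.001,0.000,0.002,0.001,0.000
5,0.018,0.001,0.000,0.004,0.001,0.000
6,0.017,0.001,0.000,0.004,0.001,0.000
7,0.015,0.002,0.000,0.004,0.001,0.000
8,0.016,0.003,0.000,0.006,0.001,0.000
9,0.044,0.006,0.000,0.016,0.001,0.000
10,0.033,0.009,0.000,0.016,0.001,0.000
11,0.008,0.036,0.006,0.015,0.006,0.014
12,0.007,0.053,0.007,0.018,0.006,0.019
13,0.007,0.055,0.008,0.017,0.007,0.021
14,0.006,0.048,0.005,0.016,0.005,0.016
15,0.008,0.032,0.002,0.014,0.003,0.008
16,0.007,0.036,0.002,0.014,0.004,0.009
17,0.007,0.027,0.001,0.013,0.003,0.006
18,0.008,0.036,0.001,0.016,0.003,0.006
19,0.009,0.035,0.001,0.017,0.002,0.005
20,0.010,0.062,0.001,0.023,0.003,0.008
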