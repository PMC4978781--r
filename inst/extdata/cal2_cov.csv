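item_id,var_a,var_b,var_c,cov_ab,cov_ac,cov_bc
1,0.019,0.004,0.012,0.002,0.012,0.005
2,0.017,0.002,0.003,0.000,0.006,0.001
3,0.015,0.001,0.001,0.000,0.003,0.001
4,0.009,0.001,0.001,0.001,0.002,0.001
5,0.010,0.001,0.000,0.002,0.002,0.001
6,0.011,0.001,0.000,0.001,0.001,0.000
7,0.009,0.001,0.000,0.002,0.001,0.001
8,0.014,0.002,0.000,0.004,0.001,0.000
9,0.020,0.003,0.000,0.007,0.001,0.000
10,0.022,0.006,0.000,0.011,0.001,0.001
11,0.009,0.215,0.031,0.039,0.015,0.081
12,0.009,0.292,0.036,0.047,0.017,0.103
13,0.008,0.180,0.021,0.034,0.012,0.061
14,0.007,0.125,0.015,0.027,0.009,0.043
15,0.007,0.073,0.007,0.020,0.006,0.022
16,0.007,0.109,0.009,0.026,0.008,0.031
17,0.007,0.152,0.011,0.031,0.008,0.040
18,0.008,0.066,0.004,0.021,0.005,0.015
19,0.009,0.136,0.005,0.033,0.006,0.025
20,0.010,0.139,0.004,0.034,0.006,0.023
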