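item_id,a,b,c
1,2.612,-0.843,0.213
2,2.707,-0.558,0.234
3,2.612,-0.297,0.232
4,2.751,-0.008,0.241
5,2.830,0.283,0.258
6,2.722,0.296,0.264
7,2.596,0.536,0.241
8,2.506,0.773,0.231
9,3.150,1.090,0.249
10,2.605,1.331,0.246
11,1.022,-0.652,0.295
12,0.897,-0.523,0.245
13,0.860,-0.510,0.171
14,0.854,-0.209,0.181
15,0.938,0.311,0.246
16,0.904,0.205,0.233
17,0.971,0.497,0.244
18,0.924,0.841,0.248
19,0.946,1.087,0.245
20,0.826,1.352,0.225
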