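item_id,a,b,c
1,2.162,-1.725,0.191
2,2.334,-1.333,0.212
3,2.358,-0.959,0.290
4,2.125,-0.728,0.228
5,2.140,-0.364,0.238
6,2.283,-0.338,0.248
7,2.013,-0.046,0.233
8,2.183,0.330,0.253
9,2.478,0.663,0.257
10,2.176,1.004,0.249
11,0.745,-1.518,0.284
12,0.685,-1.486,0.256
13,0.698,-1.071,0.234
14,0.715,-0.857,0.187
15,0.770,-0.447,0.225
16,0.715,-0.455,0.228
17,0.647,-0.276,0.173
18,0.762,0.248,0.227
19,0.655,0.562,0.229
20,0.647,0.860,0.216
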