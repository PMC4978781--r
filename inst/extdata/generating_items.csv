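item_id,a,b,c
1,1.500,-2.000,0.250
2,1.500,-1.500,0.250
3,1.500,-1.000,0.250
4,1.500,-0.500,0.250
5,1.500,0.000,0.250
6,1.500,0.000,0.250
7,1.500,0.500,0.250
8,1.500,1.000,0.250
9,1.500,1.500,0.250
10,1.500,2.000,0.250
11,0.500,-2.000,0.250
12,0.500,-1.500,0.250
13,0.500,-1.000,0.250
14,0.500,-0.500,0.250
15,0.500,0.000,0.250
16,0.500,0.000,0.250
17,0.500,0.500,0.250
18,0.500,1.000,0.250
19,0.500,1.500,0.250
20,0.500,2.000,0.250
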