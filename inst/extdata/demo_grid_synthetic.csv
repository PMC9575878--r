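size,f1
1,0.55
2,0.62
3,0.68
4,0.73
5,0.78
6,0.82
7,0.855
8,0.885
9,0.91
10,0.93
11,0.9
12,0.9025
13,0.905
14,0.9075
15,0.91
16,0.9125
17,0.915
18,0.9175
19,0.92
20,0.9225
21,0.925
22,0.9275
23,0.93
24,0.9325
25,0.935
26,0.9375
27,0.94
28,0.9425
29,0.945
30,0.931
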