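"embryo","delay_frac"
1,0.0862
2,0.1472
3,0.1049
4,0.1116
5,0.0303
6,0.0213
7,0.2139
8,0.2026
9,0.1794
10,0.0812
11,0.061
12,0.1166
13,0.0565
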