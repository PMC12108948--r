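angle,trough
-15,854
-10,785
-5,516
0,407
5,261
6,179
7,135
8,78
9,42
10,40
11,36
12,45
10,40
15,281
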