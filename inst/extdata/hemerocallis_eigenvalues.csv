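component,eigenvalue,contribution_pct,cumulative_pct
1,4.278,32.909,32.909
2,3.109,23.919,56.828
3,2.241,17.235,74.063
4,1.017,7.82,81.883
5,0.705,5.421,87.304
6,0.421,3.24,90.543
7,0.385,2.963,93.506
8,0.286,2.197,95.703
9,0.253,1.95,97.653
10,0.208,1.598,99.251
11,0.087,0.668,99.919
12,0.01,0.076,99.995
13,0.001,0.005,100
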