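index,PC1,PC2,PC3
PH,0.909,-0.097,-0.079
CW,0.821,0.169,-0.061
LL,0.939,0.027,0.05
LW,0.141,-0.004,0.939
LA,0.697,-0.009,0.678
Chl,-0.179,0.887,-0.116
Chl_a,-0.164,0.905,-0.126
Chl_b,-0.125,0.467,0.132
Chl_ab,0.058,-0.196,-0.059
Car,0.186,0.809,0.225
RWC,0.135,0.029,-0.764
EL,0.784,-0.351,0.001
MDA,0.152,-0.112,-0.663
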