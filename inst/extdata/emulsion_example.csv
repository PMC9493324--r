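ratio_label,A_0,A_10,C_mg_per_mL,oil_fraction,dilution
0%,0.50,0.300,1,0.25,100
2%,0.47,0.306,1,0.25,100
4%,0.44,0.308,1,0.25,100
6%,0.41,0.308,1,0.25,100
8%,0.38,0.304,1,0.25,100
10%,0.35,0.298,1,0.25,100
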