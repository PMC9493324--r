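ratio_label,A_C,A_0
0%,0.560,0.800
2%,0.524,0.800
4%,0.488,0.800
6%,0.452,0.800
8%,0.416,0.800
10%,0.380,0.800
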