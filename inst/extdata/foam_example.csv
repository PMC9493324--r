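ratio_label,V_a,V_b,V_F0,V_Ft,t_min
0%,60,50,10,5.0,20
2%,62,50,12,6.7,20
4%,64,50,14,8.7,20
6%,66,50,16,10.9,20
8%,68,50,18,13.3,20
10%,70,50,20,16.0,20
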