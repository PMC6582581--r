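"hu","density_g_cm3"
-1000,0.00121
0,1
1000,1.6
3000,2.5
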