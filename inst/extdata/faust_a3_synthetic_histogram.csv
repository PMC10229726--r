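"bin_low_deg","bin_high_deg","frequency"
0,10,0
10,20,0
20,30,2e-04
30,40,0.0026
40,50,0.0243
50,60,0.1102
60,70,0.2406
70,80,0.3088
80,90,0.3132
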