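x_mm,y_mm,weight_gy
-5,-5,1.5
0,-5,1.2
5,-5,1.5
-5,0,1.2
0,0,1
5,0,1.2
-5,5,1.5
0,5,1.2
5,5,1.5
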