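metal,min,max,mean,sd
Cd,0.08,17.32,2.52,4.31
Cr,22.61,109.54,58.74,20.18
Cu,10.50,60.23,31.39,11.77
Zn,92.60,398.83,186.28,66.92
Ni,9.52,59.27,27.00,10.49
Pb,15.51,66.08,34.89,13.60
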