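treatment,sex,histology,margin,proportion,age_mean,age_sd
0,0,0,0,0.02,12.05,4.44
0,0,0,1,0.12,17.04,7.35
0,0,1,0,0.01,11.06,2.48
0,0,1,1,0.05,13.72,5.17
0,1,0,0,0.01,12.48,1.30
0,1,0,1,0.17,16.70,6.93
0,1,1,0,0.02,14.30,2.77
0,1,1,1,0.09,16.07,5.19
1,0,0,0,0.01,14.60,2.33
1,0,0,1,0.08,15.35,6.24
1,0,1,0,0.01,13.85,6.12
1,0,1,1,0.09,14.34,5.49
1,1,0,0,0.03,15.87,4.04
1,1,0,1,0.14,18.54,6.02
1,1,1,0,0.01,10.63,2.98
1,1,1,1,0.14,17.11,5.64
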