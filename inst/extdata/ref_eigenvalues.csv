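speed_mps,component,variance,pct_var,cum_pct_var
15,1,5.144,85.734,85.734
15,2,0.324,5.400,91.134
15,3,0.273,4.546,95.680
15,4,0.180,2.995,98.676
15,5,0.060,1.008,99.694
15,6,0.019,0.316,100
20,1,3.410,68.195,68.195
20,2,1.487,29.739,97.935
20,3,0.090,1.797,99.732
20,4,0.010,0.190,99.922
20,5,0.004,0.078,100.00
25,1,3.274,65.484,65.484
25,2,1.357,27.133,92.618
25,3,0.296,5.916,98.534
25,4,0.062,1.242,99.776
25,5,0.011,0.224,100
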