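prostate,cgidc_p1_cm2,cgidc_p2_cm2,cgidc_wdsc
6,0.91,0.012,0.01
7,0.21,0.16,0.63
9,0.09,0.16,0.39
10,1.87,2.28,0.79
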