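category,pos_p1,pos_p2,kappa_printed
any_pca,48,48,1.000
cspca,45,48,0.915
gp3,43,43,0.727
gp4,45,48,0.915
gp5,1,2,0.000
minor_pattern5,7,3,0.357
cg_idc,13,16,0.701
prostatitis,17,21,0.507
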