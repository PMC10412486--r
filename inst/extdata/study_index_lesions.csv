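prostate,areaP1,areaP2,ggP1,ggP2,dsc
1,0.26,0.28,2,2,0.76
2,0.35,0.32,4,3,0.90
3,1.23,1.20,3,3,0.95
4,2.05,1.77,3,3,0.90
5,2.80,3.03,2,3,0.90
6,3.07,3.31,3,3,0.94
7,2.85,2.26,2,2,0.84
8,1.81,1.84,3,5,0.80
9,5.18,5.78,2,2,0.94
10,9.63,9.66,3,3,0.97
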