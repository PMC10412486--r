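prostate,rps_surface_cm2,pca_p1_cm2,pca_p2_cm2,pca_wdsc,cspca_p1_cm2,cspca_p2_cm2,cspca_wdsc
1,95.0,0.30,0.31,0.74,0.26,0.28,0.76
2,93.9,0.92,0.77,0.84,0.70,0.77,0.81
3,94.6,1.31,1.30,0.94,1.29,1.28,0.94
4,46.7,2.05,2.05,0.87,2.05,1.77,0.90
5,69.1,2.83,3.44,0.87,2.82,3.44,0.87
6,144.7,3.49,3.83,0.91,3.05,3.68,0.89
7,76.9,3.88,3.25,0.87,3.71,3.04,0.86
8,22.5,4.44,4.29,0.82,4.21,3.95,0.82
9,22.6,5.19,5.73,0.94,5.17,5.73,0.94
10,19.9,9.73,9.60,0.96,8.96,7.08,0.85
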