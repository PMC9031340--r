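alpha,fold1,fold2,fold3,fold4,fold5,average,sd,p_value
0.1,0.68,0.53,0.60,0.58,0.63,0.60,0.06,0.01
0.3,0.60,0.70,0.70,0.70,0.43,0.63,0.12,0.28
0.5,0.58,0.58,0.60,0.70,0.73,0.64,0.07,0.27
0.7,0.85,0.70,0.60,0.70,0.65,0.70,0.09,0.25
0.9,0.58,0.60,0.60,0.60,0.68,0.61,0.04,0.07
1.0,0.75,0.65,0.68,0.58,0.70,0.67,0.06,NA
1.1,0.68,0.75,0.75,0.73,0.75,0.73,0.03,0.09
1.3,0.63,0.73,0.68,0.75,0.70,0.70,0.05,0.32
1.5,0.70,0.78,0.85,0.80,0.88,0.80,0.07,0.03
1.7,0.80,0.73,0.63,0.75,0.78,0.74,0.07,0.07
1.9,0.75,0.73,0.73,0.75,0.83,0.76,0.05,0.02
2.1,0.68,0.63,0.60,0.62,0.575,0.63,0.04,0.12
2.3,0.73,0.73,0.73,0.73,0.70,0.72,0.01,0.09
2.5,0.75,0.58,0.68,0.68,0.60,0.66,0.07,0.34
2.7,0.68,0.53,0.45,0.63,0.60,0.58,0.09,0.04
2.9,0.73,0.73,0.73,0.75,0.73,0.73,0.01,0.07
3.1,0.70,0.55,0.65,0.57,0.63,0.62,0.06,0.02
3.3,0.65,0.65,0.65,0.58,0.55,0.62,0.05,0.07
3.5,0.73,0.75,0.73,0.75,0.70,0.73,0.02,0.08
3.7,0.73,0.70,0.60,0.60,0.58,0.64,0.07,0.20
3.9,0.68,0.70,0.55,0.58,0.53,0.61,0.08,0.09
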