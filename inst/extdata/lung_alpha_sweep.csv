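alpha,fold1,fold2,fold3,fold4,fold5,average,sd,p_value
0.1,0.58,0.58,0.47,0.58,0.63,0.57,0.06,0.23
0.3,0.58,0.58,0.58,0.58,0.68,0.60,0.04,0.13
0.5,0.63,0.58,0.52,0.58,0.52,0.56,0.03,0.26
0.7,0.58,0.58,0.63,0.63,0.58,0.60,0.03,0.13
0.9,0.63,0.53,0.68,0.47,0.53,0.57,0.08,0.21
1.0,0.73,0.47,0.47,0.47,0.47,0.52,0.12,NA
1.1,0.63,0.63,0.52,0.52,0.52,0.56,0.06,0.18
1.3,0.68,0.53,0.53,0.47,0.53,0.55,0.08,0.15
1.5,0.58,0.53,0.53,0.47,0.53,0.53,0.04,0.44
1.7,0.73,0.47,0.63,0.57,0.42,0.56,0.12,0.37
1.9,0.69,0.63,0.58,0.53,0.68,0.62,0.07,0.04
2.1,0.79,0.84,0.73,0.79,0.79,0.79,0.04,0.004
2.3,0.84,0.78,0.84,0.73,0.84,0.81,0.05,0.002
2.5,0.79,0.84,0.74,0.68,0.63,0.74,0.08,0.007
2.7,0.79,0.74,0.69,0.74,0.74,0.74,0.04,0.003
2.9,0.79,0.79,0.79,0.79,0.73,0.78,0.03,0.004
3.1,0.74,0.74,0.78,0.78,0.68,0.74,0.04,0.008
3.3,0.79,0.79,0.74,0.74,0.74,0.76,0.03,0.003
3.5,0.74,0.73,0.68,0.33,0.58,0.61,0.17,0.12
3.7,0.68,0.63,0.47,0.63,0.73,0.63,0.09,0.07
3.9,0.78,0.53,0.47,0.47,0.63,0.58,0.13,0.07
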