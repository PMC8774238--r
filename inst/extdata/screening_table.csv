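method,feature,p_value,median_pos,iqr_pos_lo,iqr_pos_hi,median_neg,iqr_neg_lo,iqr_neg_hi
fisher,Perc10,<0.001,32.8,24,38,8.12,6,14
fisher,WavEnHH_s-2,0.0013,8.5,3.95,10.87,15.8,11,20.1
fisher,CN6D4Contrast,<0.001,32.15,24.3,37.8,18.6,8.6,22.14
fisher,Teta3,0.6,0.17,0.01,0.41,0.19,0.13,0.61
fisher,Kurtosis,0.33,10.6,0.13,68.4,18.8,28.2,59.3
fisher,CN6D5Correlat,0.06,0.58,0.51,0.77,0.51,0.26,0.64
fisher,RZD5GLevNonU,<0.001,3041.8,1310.7,3969.2,1081.2,641.01,1922.92
fisher,RZD3Fraction,0.041,0.77,0.7,0.81,0.68,0.41,0.77
fisher,CH5D4DifVarnc,<0.001,20.43,12.51,24.8,6.23,3.3,15.6
fisher,Perc50,0.07,19.24,11,26,16.43,7,25
poe_acc,CZ2D4DifVarnc,<0.001,22.13,12.94,26.11,7.26,3.81,15.41
poe_acc,WavEnHL_s-3,<0.001,10.65,5.33,21.12,28.68,16.2,38.02
poe_acc,CV3S6SumAverg,0.049,64.15,39.12,84.9,52.8,26.7,74.17
poe_acc,RVD6LngREmph,0.62,2.31,1.81,3.19,5.73,2.46,38.14
poe_acc,CZ5S6Correlat,0.01,0.56,0.21,0.82,0.29,0.01,0.65
poe_acc,CN4S6Entropy,0.03,1.13,0.04,2.27,3.01,1.7,5.89
poe_acc,CV1S6AngScMom,0.46,0.12,0.01,0.22,0.29,0.06,0.36
poe_acc,Perc10,<0.001,32.8,24,38,8.12,6,14
poe_acc,WavEnHH_s-2,0.0013,8.5,3.95,10.87,15.8,11,20.1
poe_acc,RZD5GLevNonU,<0.001,3041.8,1310.7,3969.2,1081.2,641.01,1922.92
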