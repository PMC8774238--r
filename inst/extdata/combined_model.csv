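quantity,value
sensitivity_pct,93.33
specificity_pct,100
criterion,0.57
auc,0.992
auc_ci_lo,0.903
auc_ci_hi,1
r2,0.7153
r2_adjusted,0.6583
mcc,0.8457
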