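name,value
n,31
p,3
r2,0.783
sec,0.276
f_value,32.521
f_crit,2.960
q2_loo,0.618
sev,0.342
press,3.621
ssy,9.491
lv1_pct,18.043
lv2_pct,31.298
lv3_pct,22.504
cum_pct,71.845
coef_SOFT,0.394
coef_EEig02r,-2.198
coef_alpha_xx,0.014
coef_q10NBO,80.105
coef_q2NBO,11.339
coef_SsssN_oth,-9.218
intercept,64.222
std_SOFT,0.545
std_EEig02r,-0.549
std_alpha_xx,0.377
std_q10NBO,0.238
std_q2NBO,0.250
std_SsssN_oth,-0.314
wold_threshold,0.274
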