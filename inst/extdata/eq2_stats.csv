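name,value
n,26
p,3
r2,0.809
sec,0.264
f_value,31.089
f_crit,3.049
q2_loo,0.626
sev,0.340
press,3.000
ssy,8.026
coef_SOFT,0.450
coef_EEig01x,-2.293
coef_alpha_xx,0.013
coef_q10NBO,61.930
coef_q2NBO,14.508
coef_SsssN_oth,-8.637
intercept,55.156
std_SOFT,0.599
std_EEig01x,-0.579
std_alpha_xx,0.362
std_q10NBO,0.149
std_q2NBO,0.322
std_SsssN_oth,-0.278
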