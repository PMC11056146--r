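parameter,class,estimate,ci_low,ci_high,p_raw,p_adj_published,n
FA,progressing_wmh,-0.022,-0.027,-0.017,8.99e-15,NA,195
FA,regressing_wmh,0.011,0.006,0.017,3.28e-5,NA,195
FA,stable_wmh,-0.009,-0.011,-0.006,6.59e-11,NA,195
FA,stable_nawm,-0.002,-0.004,-0.000,0.017,0.068,195
MD,progressing_wmh,0.057,0.050,0.063,6.07e-41,NA,195
MD,regressing_wmh,-0.002,-0.008,0.003,0.363,0.726,195
MD,stable_wmh,0.054,0.045,0.063,2.05e-25,NA,195
MD,stable_nawm,0.004,0.003,0.005,1.11e-12,NA,195
T1,progressing_wmh,0.058,0.050,0.066,1.01e-30,NA,182
T1,regressing_wmh,-0.003,-0.009,0.004,0.412,0.726,182
T1,stable_wmh,0.049,0.039,0.058,6.23e-20,NA,182
T1,stable_nawm,0.005,0.001,0.009,0.020,0.068,182
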