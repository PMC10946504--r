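state,level_ols,level_ols_se,level_reml,level_reml_se,slope_ols,slope_ols_se,slope_reml,slope_reml_se,autocorrelation
State 1,0.96,0.43,0.72,0.60,0.01,0.02,0.01,0.02,0.37
State 2,0.73,0.54,1.09,0.73,0.11,0.06,0.11,0.06,0.42
State 3,-0.07,0.42,-0.01,0.64,0.03,0.02,0.03,0.02,0.49
State 4,-0.36,0.42,-0.34,0.58,0.04,0.02,0.04,0.02,0.36
State 5,0.56,0.42,0.56,0.66,0.00,0.02,0.00,0.02,0.55
State 6,0.68,0.54,0.76,0.62,-0.03,0.06,-0.03,0.06,0.17
State 7,0.08,0.42,0.10,0.48,0.02,0.02,0.02,0.02,0.16
State 8,-0.38,0.42,-0.27,0.54,0.00,0.02,0.00,0.02,0.28
State 9,0.25,0.54,0.25,0.71,0.06,0.06,0.06,0.06,0.38
State 10,0.25,0.42,0.36,0.70,0.01,0.02,0.01,0.02,0.63
State 11,0.05,0.43,-0.12,0.56,0.02,0.02,0.02,0.02,0.29
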