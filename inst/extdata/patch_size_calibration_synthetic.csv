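"rho_m","u_intercept_mean_m","u_intercept_sd_m","zero_intercept_mean_m"
400,2949,261,2929
700,2924,138,2915
1000,3029,294,3025
1100,3192,387,3182
1200,3530,533,3512
1300,3941,522,3887
1600,4606,173,4563
2000,5127,255,5059
3000,6888,220,6831
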