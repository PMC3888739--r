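true_slope_a: -100
true_intercept_b: 300
times_days: 1,2,3,4
noise_sd: 10
n_series: 50
seed: 1
noise: gaussian
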