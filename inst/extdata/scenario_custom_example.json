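{
  "name": "custom",
  "theta_prior": { "alpha": 1, "beta": 399 },
  "s_prior": { "alpha": 21, "beta": 9 },
  "intercept_prior": { "mean": -3, "variance": 10 },
  "coef_prior": { "mean": 0, "variance": 10000 }
}
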