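{
  "a1": 0.9,
  "a2": 0.1,
  "p0": 0.02,
  "t_star_days": 60,
  "threshold_times_pmax": false,
  "width_equation": "l1",
  "rho_hat_bracket": [0.05, 50],
  "rho_bracket": [0.001, 2],
  "shapes": { "alpha_g": 2, "beta_g": 2, "alpha_d": 1, "beta_d": 3 }
}
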