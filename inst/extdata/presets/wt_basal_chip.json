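{
  "name": "wt_basal_chip",
  "description": "Wild-type (N2) basal pumping, on-chip recording",
  "freq_mean": 0.075, "freq_cv": 0.3,
  "dur_mean": 0.116, "dur_cv": 0.1,
  "p_rate": 1.788,
  "amp_pp_mean": 4.410, "amp_pp_cv": 0.1,
  "e_amp_mean": 0.257,
  "re_ratio_mean": 1.222,
  "worm_cv": 0.10
}
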