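{
  "name": "wt_basal_conventional",
  "description": "Wild-type (N2) basal pumping, conventional suction microelectrode",
  "freq_mean": 0.060, "freq_cv": 0.3,
  "dur_mean": 0.112, "dur_cv": 0.1,
  "p_rate": 0.590,
  "amp_pp_mean": 4.780, "amp_pp_cv": 0.1,
  "e_amp_mean": 0.203,
  "re_ratio_mean": 1.006,
  "worm_cv": 0.10
}
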