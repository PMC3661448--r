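{
  "name": "wt_5ht_conventional",
  "description": "Wild-type (N2) with 10 mM serotonin, conventional suction microelectrode",
  "freq_mean": 1.878, "freq_cv": 0.3,
  "dur_mean": 0.135, "dur_cv": 0.1,
  "p_rate": 0.201,
  "amp_pp_mean": 7.580, "amp_pp_cv": 0.1,
  "e_amp_mean": 1.080,
  "re_ratio_mean": 1.046,
  "worm_cv": 0.10
}
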