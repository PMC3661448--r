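{
  "name": "wt_5ht_chip",
  "description": "Wild-type (N2) stimulated with 10 mM serotonin, on-chip recording",
  "freq_mean": 3.467, "freq_cv": 0.3,
  "dur_mean": 0.101, "dur_cv": 0.1,
  "p_rate": 0.126,
  "amp_pp_mean": 8.370, "amp_pp_cv": 0.1,
  "e_amp_mean": 1.753,
  "re_ratio_mean": 1.143,
  "worm_cv": 0.10
}
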