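{
  "name": "tail",
  "description": "Worm trapped tail-first: pump-rate-matched monophasic blips at a quarter of the head amplitude, no e/P/r structure",
  "freq_mean": 0.075, "freq_cv": 0.3,
  "dur_mean": 0.116, "dur_cv": 0.1,
  "p_rate": 0,
  "amp_pp_mean": 0.970, "amp_pp_cv": 0.1,
  "e_amp_mean": 0,
  "re_ratio_mean": 1.0,
  "worm_cv": 0.10
}
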