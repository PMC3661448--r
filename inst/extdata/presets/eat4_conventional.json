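{
  "name": "eat4_conventional",
  "description": "eat-4 mutant, conventional suction microelectrode. Peak-to-peak amplitude is not reported for this genotype; the wild-type conventional value is reused (synthetic stand-in).",
  "freq_mean": 0.055, "freq_cv": 0.3,
  "dur_mean": 0.287, "dur_cv": 0.1,
  "p_rate": 0.280,
  "amp_pp_mean": 4.780, "amp_pp_cv": 0.1,
  "e_amp_mean": 0.368,
  "re_ratio_mean": 2.170,
  "worm_cv": 0.10
}
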