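{
  "name": "eat4_chip",
  "description": "eat-4 vesicular glutamate transporter mutant, on-chip recording. Peak-to-peak amplitude is not reported for this genotype; the wild-type on-chip value is reused (synthetic stand-in).",
  "freq_mean": 0.090, "freq_cv": 0.3,
  "dur_mean": 0.172, "dur_cv": 0.1,
  "p_rate": 0.103,
  "amp_pp_mean": 4.410, "amp_pp_cv": 0.1,
  "e_amp_mean": 0.376,
  "re_ratio_mean": 1.491,
  "worm_cv": 0.10
}
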