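# Example cohort-generator configuration (all keys optional; defaults are
# the calibrated study configuration).
"n": 38   # quoted: bare n is a YAML 1.1 boolean token
seed: 1
la_pra_latent_rho: 0.9517     # calibrated: index-vs-TA Spearman 0.948
delta_baseline_coupling: 0.8
grader_ccc_targets:
  la: 0.997
  pra: 0.962
prop_female: 0.6052631578947368
flip_delta_bcva_sign: false
margin_family: piecewise
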