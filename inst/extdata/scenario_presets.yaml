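# Frozen scenario presets (version 1): generator overrides relative to the
# calibrated configuration, tuned once to represent the study's three
# dietary-pattern groups (healthy: all index means >= 70; unhealthy: all
# <= 30; mixed: index means near MEDAS 55, DPI 25, HEI 65). The mixed
# preset decouples the protective-food pathway from the latent factor.
healthy:
  latent_shape_a: 4.7
  latent_shape_b: 0.3
unhealthy:
  latent_shape_a: 0.38
  latent_shape_b: 4.62
mixed:
  latent_shape_a: 4.05
  latent_shape_b: 0.95
  lambda_K: 0.0
  alpha_K: 2.0
  beta_K: 6.0
  lambda_M: 0.16
  lambda_Q: 0.135
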