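# Full-study configuration reproducing the production run:
# 10000 calibrated profiles (generator defaults come from the frozen
# calibrated fixture), default DDRS weights, scenario thresholds 70/30,
# +/-20% weight sensitivity, convergence grid 1000..12000, master seed 42.
# Any generator_config() field may be overridden under `generator:`.
generator:
  n_profiles: 10000
weights:
  w_S: 0.40
  w_A: 0.20
  w_K: 0.25
  w_Q: 0.15
scenario_spec:
  healthy_min: 70
  unhealthy_max: 30
sensitivity_pct: 0.20
convergence_grid: [1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000, 9000, 10000, 11000, 12000]
scenario_n: 2000
seed: 42
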