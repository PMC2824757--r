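experiment: fig5
seed: 1.0
out_dir: out/fig5
parameters:
  amplitude: 1.5
  tau_lam: 2400.0
  tau_r: 1200.0
  n_trials: 100.0
  n_events: 30000.0
  n_grid: 256.0
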