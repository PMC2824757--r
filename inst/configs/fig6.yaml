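experiment: fig6
seed: 1.0
out_dir: out/fig6
parameters:
  amplitude: 22.0
  tau_lam: 38400.0
  tau_r: 38400.0
  n_trials: 150.0
  n_events: 3200000.0
  n_grid: 512.0
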