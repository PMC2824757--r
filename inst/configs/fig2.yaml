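experiment: fig2
seed: 1.0
out_dir: out/fig2
parameters:
  g_sweep:
  - 0.0
  - 1.0
  - 2.0
  t_total: 40.0
  n_bins: 32.0
  n_seeds: 3.0
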