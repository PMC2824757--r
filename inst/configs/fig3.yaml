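experiment: fig3
seed: 1.0
out_dir: out/fig3
parameters:
  t_total: 400.0
  corr_width: 0.25
  corr_stride: 0.125
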