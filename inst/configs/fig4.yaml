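experiment: fig4
seed: 1.0
out_dir: out/fig4
parameters:
  settings:
  - g: 1.0
    tau_s: 0.002
  - g: 1.25
    tau_s: 0.005
  - g: 1.75
    tau_s: 0.01
  phi:
  - 0.0
  - 0.392699081698724
  - 0.785398163397448
  - 1.178097245096172
  - 1.570796326794897
  - 1.963495408493621
  - 2.356194490192345
  - 2.748893571891069
  - 3.141592653589793
  window: 10.0
  n_seeds: 5.0
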