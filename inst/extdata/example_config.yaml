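# Example run configuration: the default paired tumor/normal study design
# (4 patients per preparation, 3 technical repeats, 25-37 degC ramp).
study:
  patients_per_preparation: 4
  repeats_per_block: 3
  setpoints_c: [25, 28, 31, 34, 37]
  noise_cv: 0.02
  ambient_c: 20
  seed: 1
  chip:
    d1_um: 130
    d2_um: 140
  calib:
    r0_ohm: 100
    t0_c: 25
    alpha_per_c: 0.0022
stats:
  alpha: 0.05
  fold_threshold: 3.8
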