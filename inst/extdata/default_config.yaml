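design:
  temperatures: [23, 37, 60, 90]
  replicates: 18
  base_volume_ul: 11
  volume_jitter: 0.05
properties:
  lambda: 0.52
  rho: 1.04873
  cp: 3617
  ht: 35
  sigma_fit:
    a: -11.5
    b: 88.0
analysis:
  alpha_mode: si
  include_thermal: true
  grid_px: 64
  deposit_px: 128
seed: 1
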