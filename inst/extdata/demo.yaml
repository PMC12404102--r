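# Demo pipeline configuration: tiny phantoms end to end.
seed: 7
phantom:
  n_per_class: [3, 3, 3]
  grid: [32, 32, 24]
  class_mode: ri-only
convert:
  mode: segmented
  m: 512
  l: 6
select:
  k: 64
  n_fps: 50
  n_riies: 14
train:
  epochs: 3
  batch_size: 4
  profile: small
  channels: 4
evaluate: {}
profile:
  points: 1024
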