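model:
  rates:
  - 1
  - 3
  - 6
  - 12
  - 18
  branch_channels: 128
  bridge_channels: 3
  scse_placement: I_and_II
  fusion_rule: literal_product
  dropout_rate: 0.1
  scse_reduction: 2
  decoder_compress_channels: 3
  seed: 1
loss:
  mu: 0.3333333
  nu: 0.3333333
  xi: 0.3333333
training:
  lr: 0.0001
  epochs: 150
  batch_size: 8
  seed: 1
  image_size: 224
  lr_floor: 1.0e-06
  threshold: 0.5
  total_epochs: 150
data:
  type: directory
  root: ~
  n_images: 30
  image_size: 224
  category_mix:
  - 1.0
  - 1.0
  - 1.0
  fractions:
  - 0.7
  - 0.15
  - 0.15
  seed: 1
  normalization: train
output:
  dir: msfa_run
ablation:
  rate_sets:
  - - 1
    - 3
    - 6
    - 12
    - 18
  - - 1
    - 2
    - 3
    - 9
    - 15
  placements:
  - I
  - II
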