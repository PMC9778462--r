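# Full-scale training profile: 256 x 256 slices, batch 32, two
# discriminator updates per generator update, 300 epochs, Adam.
generator:
  base_channels: 32
train:
  batch_size: 32
  disc_steps: 2
  epochs: 300
  lr: 1.0e-4
  split: [0.7, 0.2, 0.1]
phantom:
  height: 256
  width: 256
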