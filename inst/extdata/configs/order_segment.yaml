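# Temporal-order discrimination: segment-mode working memory vs a
# classic baseline can be compared by editing network.mode / readout.
task:
  kind: order
  n_samples: 2000
  T: 32
  n_in: 16
  motif_len: 8
  jitter: 2
  noise_rate: 0.02
network:
  hidden: [64]
  mode: segment
  mem_len: 8
  readout: fusion
  tau: 2.0
  theta: 1.0
training:
  epochs: 30
  batch_size: 32
  learning_rate: 0.001
  optimizer: adam
  loss: cross_entropy
split: [0.8, 0.2]
seeds: [1, 2, 3, 4, 5]
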