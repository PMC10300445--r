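# Desk-scale working-memory-length sweep on the uneven-density task.
# Accuracy and timing are reported per mem_len; the trend is task- and
# hardware-dependent and is not asserted anywhere.
task:
  kind: density
  n_samples: 512
  T: 32
  n_in: 16
  motif_len: 8
  jitter: 0
  noise_rate: 0.02
network:
  hidden: [32]
  mode: segment
  mem_len: 8
  readout: fusion
  tau: 2.0
  theta: 1.0
training:
  epochs: 8
  batch_size: 32
  learning_rate: 0.001
  optimizer: adam
  loss: cross_entropy
split: [0.8, 0.2]
seeds: [1, 2]
sweep: [1, 2, 4, 8]
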