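# Example scenario override: a small two-round run with a lighter predictor.
seed: 123
n_scale: 0.25
federation:
  rounds: 5
  local_epochs: 2
  batch_size: 8
  seed: 123
predictor:
  kind: linear
  learning_rate: 0.001
association:
  restarts: 3
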