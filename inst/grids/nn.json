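{
  "hidden": [[64, 32], [128, 64], [32, 16]],
  "activation": ["relu", "tanh"],
  "learning_rate": [0.01, 0.003],
  "weight_decay": [0, 0.0001],
  "dropout": [0, 0.2, 0.4],
  "epochs": [100, 200]
}
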