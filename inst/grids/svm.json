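{
  "kernel": ["linear", "radial"],
  "cost": [0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30],
  "gamma": [0.0001, 0.0003, 0.001, 0.003, 0.01, 0.03, 0.1, 0.3]
}
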