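{
  "nrounds": [50, 100, 200],
  "max_depth": [2, 3, 4, 6],
  "eta": [0.05, 0.1, 0.3],
  "subsample": [0.8, 1],
  "colsample_bytree": [0.5, 1]
}
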