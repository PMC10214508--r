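{
  "num_trees": [100, 250, 500, 1000, 1500],
  "mtry": [0.05, 0.1, 0.2, 0.33, 0.5],
  "min_node_size": [1, 2, 3, 5, 10]
}
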