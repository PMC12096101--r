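{
  "mu": 0.75,
  "N": 40,
  "L": 120,
  "T": 1000,
  "seed": 42,
  "n_runs": 10,
  "sweep": { "mu": [0.25, 0.5, 0.75, 1.0] }
}
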