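{
  "n_points": 10000,
  "turns": 3,
  "noise_sd": 0.1,
  "embed_dim": 31,
  "embed_seed": 1,
  "inner_radius": 0.2
}
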