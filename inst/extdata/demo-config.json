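{
  "seed": 42,
  "sim": {
    "n_tfs": 80,
    "n_background_genes": 400,
    "n_archetypes": 12,
    "noise_sd": 0.1
  },
  "cluster": {
    "k": 12,
    "n_init": 5
  },
  "screen": {
    "r_threshold": 0.8,
    "alpha": 0.05,
    "min_count": 5,
    "require_both": true
  },
  "log_level": "warn"
}
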