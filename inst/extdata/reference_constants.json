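[
  {
    "experiment": "normalization",
    "measure": "slope_pairs",
    "value": 0.5,
    "provenance": "Average-of-parts slope for two-object displays measured in single-unit recordings from macaque inferior temporal cortex; the canonical signature of divisive normalization."
  },
  {
    "experiment": "normalization",
    "measure": "slope_triplets",
    "value": 0.33,
    "provenance": "Average-of-parts slope for three-object displays measured in single-unit recordings from macaque inferior temporal cortex."
  }
]
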