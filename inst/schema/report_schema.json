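{
  "title": "scatdiet analysis report",
  "required_top_level": {
    "config": "object",
    "n_records": "integer",
    "predators": "object",
    "joint": "object"
  },
  "required_per_predator": [
    "n_scats",
    "occurrence_counts",
    "rfo_percent",
    "origin_rfo",
    "levins",
    "levins_ci",
    "boot_seed",
    "composition",
    "accumulation"
  ]
}
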