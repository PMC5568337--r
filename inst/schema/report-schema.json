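{
  "type": "object",
  "required": ["cohort_summary", "stages", "provenance"],
  "properties": {
    "cohort_summary": {
      "type": "object",
      "required": ["group", "n", "age_mean", "age_sd", "pct_male",
                   "max_iop_mean", "max_iop_sd", "vcdr_mean", "vcdr_sd"],
      "properties": {
        "group": {"type": "array", "items": {"type": "string"}},
        "n": {"type": "array", "items": {"type": "number"}},
        "age_mean": {"type": "array", "items": {"type": "number"}},
        "age_sd": {"type": "array", "items": {"type": "number"}},
        "pct_male": {"type": "array", "items": {"type": "number"}},
        "max_iop_mean": {"type": "array", "items": {"type": "number"}},
        "max_iop_sd": {"type": "array", "items": {"type": "number"}},
        "vcdr_mean": {"type": "array", "items": {"type": "number"}},
        "vcdr_sd": {"type": "array", "items": {"type": "number"}}
      }
    },
    "stages": {
      "type": "object",
      "required": ["scores", "linear_iop_variants", "linear_iop_grs",
                   "linear_vcdr_grs", "linear_iop_vcdr", "anova_grs",
                   "logistic_ntg", "logistic_htg", "cutoff_scan"],
      "properties": {
        "linear_iop_variants": {"type": "object"},
        "linear_iop_grs": {"type": "object"},
        "linear_vcdr_grs": {"type": "object"},
        "linear_iop_vcdr": {"type": "object"},
        "anova_grs": {"type": "object"},
        "logistic_ntg": {"type": "object"},
        "logistic_htg": {"type": "object"},
        "cutoff_scan": {"type": "object"},
        "scores": {"type": "object"}
      }
    },
    "provenance": {
      "type": "object",
      "required": ["seed", "config_hash", "package_version"],
      "properties": {
        "seed": {"type": "number"},
        "config_hash": {"type": "string"},
        "package_version": {"type": "string"}
      }
    }
  }
}
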