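{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "knowjudge analysis report",
  "type": "object",
  "required": ["reliability", "knowledge", "evaluator", "models", "provenance"],
  "properties": {
    "reliability": {
      "type": "object",
      "required": ["statement_type", "group", "icc"]
    },
    "knowledge": {
      "type": "object",
      "required": ["mean_selected", "mean_assigned", "difference",
                   "bf10", "bf_display", "n", "mean_category_spread"]
    },
    "evaluator": {
      "type": "object",
      "required": ["accuracy_by_level", "contrast_levels", "contrast_bf10",
                   "contrast_bf_display", "ceiling"],
      "properties": {
        "ceiling": {
          "type": "object",
          "required": ["probability", "n_splits", "n_pairs", "seed"]
        }
      }
    },
    "models": {
      "type": "object"
    },
    "provenance": {
      "type": "object",
      "required": ["seed", "config_hash", "package_version"]
    }
  }
}
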