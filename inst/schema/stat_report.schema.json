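{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "avrecal statistical report",
  "type": "object",
  "required": [
    "experiment_mode", "seed", "n_subjects_simulated", "n_subjects_analyzed",
    "exclusions", "condition_means", "inference_performed", "config"
  ],
  "properties": {
    "experiment_mode": { "enum": ["action", "visual-cue", "tactile-cue"] },
    "seed": { "type": "integer" },
    "n_subjects_simulated": { "type": "integer", "minimum": 1 },
    "n_subjects_analyzed": { "type": "integer", "minimum": 0 },
    "exclusions": {
      "type": "object",
      "properties": {
        "subject_id": { "type": "array", "items": { "type": "string" } },
        "reasons": { "type": "array", "items": { "type": "string" } }
      }
    },
    "condition_means": {
      "type": "object",
      "required": ["condition", "mean_pss_ms"],
      "properties": {
        "condition": { "type": "array", "items": { "type": "string" } },
        "mean_pss_ms": { "type": "array", "items": { "type": "number" } },
        "sd_pss_ms": { "type": "array", "items": { "type": "number" } },
        "mean_sigma_ms": { "type": "array", "items": { "type": "number" } },
        "mean_r_squared": { "type": "array", "items": { "type": "number" } }
      }
    },
    "inference_performed": { "type": "boolean" },
    "notices": { "type": "array", "items": { "type": "string" } },
    "anova": {
      "type": "object",
      "required": ["effect", "F", "df1", "df2", "p", "partial_eta_sq"]
    },
    "t_tests": {
      "type": "object",
      "required": ["contrast", "t", "df", "p_two_tailed", "mean_diff", "d_z"]
    },
    "bias_tests": {
      "type": "object",
      "required": ["condition", "t", "df", "p_two_tailed", "d_z"]
    },
    "adaptation_effect_ms": { "type": "number" },
    "achieved_power": { "type": ["number", "null"] },
    "config": { "type": "object" }
  }
}
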