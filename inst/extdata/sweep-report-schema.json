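{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "durobust sweep report",
  "type": "object",
  "required": ["model", "param", "grid", "intervals", "n_activated"],
  "properties": {
    "model": {"enum": ["heinrich", "linearized", "hf"]},
    "param": {"type": "string"},
    "grid": {
      "type": "object",
      "required": ["log_start", "log_stop", "log_step", "n_points"],
      "properties": {
        "log_start": {"type": "number"},
        "log_stop": {"type": "number"},
        "log_step": {"type": "number", "exclusiveMinimum": 0},
        "n_points": {"type": "integer", "minimum": 1}
      }
    },
    "intervals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["log10_lo", "log10_hi", "n_points"],
        "properties": {
          "log10_lo": {"type": "number"},
          "log10_hi": {"type": "number"},
          "n_points": {"type": "integer", "minimum": 1}
        }
      }
    },
    "beta_max": {"type": ["number", "null"]},
    "crossover": {"type": ["number", "null"]},
    "n_activated": {"type": "integer", "minimum": 0}
  }
}
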