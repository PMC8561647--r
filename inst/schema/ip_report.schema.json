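{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tmsfocal inverse-problem report",
  "type": "object",
  "required": ["tool", "version", "config", "config_hash", "target",
               "pose_initial", "pose_final", "metrics"],
  "properties": {
    "tool": {"const": "tmsfocal"},
    "version": {"type": "string"},
    "config": {"type": "object"},
    "config_hash": {"type": "string"},
    "target": {"type": "array", "items": {"type": "number"},
               "minItems": 3, "maxItems": 3},
    "pose_initial": {"$ref": "#/definitions/pose"},
    "pose_final": {"$ref": "#/definitions/pose"},
    "metrics": {
      "type": "object",
      "required": ["aad_initial", "aad_final", "df_initial", "df_final",
                   "improvement"],
      "properties": {
        "aad_initial": {"type": "number", "minimum": 0},
        "aad_final": {"type": "number", "minimum": 0},
        "df_initial": {"type": "number"},
        "df_final": {"type": "number"},
        "ard_initial": {"type": ["number", "null"]},
        "ard_final": {"type": ["number", "null"]},
        "field_loss": {"type": "number"},
        "peak_dev_initial": {"type": "number", "minimum": 0},
        "peak_dev_final": {"type": "number", "minimum": 0},
        "improvement": {"type": "number"}
      }
    }
  },
  "definitions": {
    "pose": {
      "type": "object",
      "required": ["center", "pitch", "roll", "yaw", "convention"],
      "properties": {
        "center": {"type": "array", "items": {"type": "number"},
                   "minItems": 3, "maxItems": 3},
        "pitch": {"type": "number"},
        "roll": {"type": "number"},
        "yaw": {"type": "number"},
        "convention": {"type": "string"}
      }
    }
  }
}
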