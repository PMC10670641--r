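{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "MammoAsym asymmetry report",
  "type": "object",
  "required": [
    "patient_id", "dtw_index", "shape_flag", "thickness_left",
    "thickness_right", "thickness_difference", "skin_flag", "params",
    "versions"
  ],
  "properties": {
    "patient_id": { "type": "string" },
    "dtw_index": { "type": "number", "minimum": 0, "maximum": 1 },
    "shape_flag": { "type": "boolean" },
    "thickness_left": { "type": "number", "minimum": 0 },
    "thickness_right": { "type": "number", "minimum": 0 },
    "thickness_difference": { "type": "number", "minimum": 0, "maximum": 1 },
    "skin_flag": { "type": "boolean" },
    "centroids": { "type": "object" },
    "params": {
      "type": "object",
      "required": [
        "threshold_T", "connectivity", "angular_step", "shape_threshold",
        "skin_threshold", "kernel", "depth", "upper", "lower"
      ]
    },
    "versions": { "type": "string" }
  }
}
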