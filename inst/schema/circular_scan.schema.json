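{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Segmented circumpapillary circular OCT scan",
  "description": "Per-sample axial layer positions (um, anterior positive) on one of the four standard circles. theta strictly increasing, span >= 359 degrees; at most 25% of samples masked.",
  "type": "object",
  "required": ["diameter_mm", "theta", "ilm_z", "rnfl_post_z", "bm_z", "choroid_sclera_z"],
  "properties": {
    "diameter_mm": { "enum": [2.7, 3.5, 4.2, 4.9] },
    "theta": { "type": "array", "items": { "type": "number" } },
    "ilm_z": { "type": "array", "items": { "type": "number" } },
    "rnfl_post_z": { "type": "array", "items": { "type": "number" } },
    "bm_z": { "type": "array", "items": { "type": "number" } },
    "choroid_sclera_z": { "type": "array", "items": { "type": "number" } },
    "valid": { "type": "array", "items": { "type": "boolean" } }
  }
}
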