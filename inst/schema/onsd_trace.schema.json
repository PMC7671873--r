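{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Optic nerve sheath ultrasound trace",
  "description": "Millimetre coordinates in the ultrasound frame. The axis polyline starts at the posterior globe; the two sheath polylines flank it. The sheath diameter is measured perpendicular to the axis 3 mm (arc length) behind the globe.",
  "type": "object",
  "required": ["globe_posterior", "axis", "sheath_upper", "sheath_lower"],
  "properties": {
    "globe_posterior": { "$ref": "#/definitions/point" },
    "axis": { "$ref": "#/definitions/polyline" },
    "sheath_upper": { "$ref": "#/definitions/polyline" },
    "sheath_lower": { "$ref": "#/definitions/polyline" }
  },
  "definitions": {
    "point": {
      "type": "array", "minItems": 2, "maxItems": 2,
      "items": { "type": "number" },
      "description": "[x_mm, z_mm]"
    },
    "polyline": {
      "type": "array", "minItems": 2,
      "items": { "$ref": "#/definitions/point" }
    }
  }
}
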