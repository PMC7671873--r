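{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Segmented radial OCT scan set",
  "description": "24 radial B-scan diameters centred on the optic nerve head. Units: micrometres. Lateral s increases along the scan line (s = 0 at the shared rotation centre); axial z increases toward the vitreous (anterior positive).",
  "type": "object",
  "required": ["eye", "axial_sign", "bscans"],
  "properties": {
    "eye": { "enum": ["OD", "OS"] },
    "axial_sign": { "const": "anterior_up" },
    "bscans": {
      "type": "array",
      "minItems": 24,
      "maxItems": 24,
      "items": {
        "type": "object",
        "required": ["index", "angle_deg", "ilm", "bm", "bmo_left", "bmo_right"],
        "properties": {
          "index": { "type": "integer", "minimum": 0, "maximum": 23 },
          "angle_deg": { "type": "number", "description": "index * 7.5" },
          "ilm": { "$ref": "#/definitions/polyline" },
          "bm": { "$ref": "#/definitions/polyline" },
          "alcs": { "$ref": "#/definitions/polyline" },
          "bmo_left": { "$ref": "#/definitions/point" },
          "bmo_right": { "$ref": "#/definitions/point" }
        }
      }
    }
  },
  "definitions": {
    "point": {
      "type": "array", "minItems": 2, "maxItems": 2,
      "items": { "type": "number" },
      "description": "[s_um, z_um]"
    },
    "polyline": {
      "type": "array", "minItems": 2,
      "items": { "$ref": "#/definitions/point" },
      "description": "strictly increasing in s"
    }
  }
}
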