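{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "information layer file (JSON dialect)",
  "type": "object",
  "required": ["information"],
  "additionalProperties": false,
  "properties": {
    "information": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["numClass", "values"],
        "properties": {
          "name": { "type": "string" },
          "numClass": { "type": "integer", "minimum": 1 },
          "labels": {
            "type": "array",
            "items": { "type": "string" },
            "description": "if present, length must equal numClass"
          },
          "values": {
            "type": "array",
            "minItems": 1,
            "items": { "type": "integer" },
            "description": "canonical form: 0-based class index per point, same order and length as the dataset's points; values occupying exactly {1..numClass} are accepted and shifted down with a warning"
          }
        }
      }
    }
  }
}
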