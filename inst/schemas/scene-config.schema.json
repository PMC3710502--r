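{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "scene configuration file",
  "description": "Reproducible description of a multi-world scene for command-line rendering. Data files are referenced by path (relative paths resolve against the config file's directory).",
  "type": "object",
  "required": ["worlds"],
  "properties": {
    "settings": {
      "type": "object",
      "properties": {
        "axis_scale": {
          "type": "array", "minItems": 3, "maxItems": 3,
          "items": { "type": "number", "exclusiveMinimum": 0 }
        },
        "raw_opacity": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
        "layer_opacity": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
        "raw_size": { "type": "number", "exclusiveMinimum": 0 },
        "layer_size": { "type": "number", "exclusiveMinimum": 0 },
        "center": { "type": "boolean" }
      }
    },
    "worlds": {
      "type": "array",
      "minItems": 1,
      "maxItems": 4,
      "items": {
        "type": "object",
        "properties": {
          "id": { "type": "integer", "minimum": 1, "maximum": 4 },
          "bindings": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["dataset"],
              "properties": {
                "dataset": { "type": "string", "description": "path to a dataset file (any dialect)" },
                "information": { "type": "string", "description": "path to an information file (any dialect)" },
                "layer_index": { "type": "integer", "minimum": 1 },
                "classes": {
                  "type": "array",
                  "description": "per-class display state, class 0 first",
                  "items": {
                    "type": "object",
                    "properties": {
                      "visible": { "type": "boolean" },
                      "colour": {
                        "type": "array", "minItems": 3, "maxItems": 3,
                        "items": { "type": "number", "minimum": 0, "maximum": 1 }
                      }
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
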