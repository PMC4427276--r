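{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "GMA model dialect",
  "description": "Generalized mass action model: variables, power-law fluxes and stoichiometric rows. Every number is a decimal string so printed constants round-trip exactly.",
  "type": "object",
  "required": ["variables", "fluxes", "rows"],
  "definitions": {
    "decimal": {
      "type": "string",
      "pattern": "^[+-]?([0-9]+([.][0-9]*)?|[.][0-9]+)([eE][+-]?[0-9]+)?$"
    }
  },
  "properties": {
    "variables": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "role", "basal"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "role": {"enum": ["tunable", "solved", "fixed"]},
          "basal": {"$ref": "#/definitions/decimal"},
          "bounds": {
            "type": "array",
            "items": {"$ref": "#/definitions/decimal"},
            "minItems": 2,
            "maxItems": 2
          }
        }
      }
    },
    "fluxes": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "rate_constant"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "rate_constant": {"$ref": "#/definitions/decimal"},
          "kinetic_orders": {
            "type": "object",
            "additionalProperties": {"$ref": "#/definitions/decimal"}
          }
        }
      }
    },
    "rows": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["pool", "terms"],
        "properties": {
          "pool": {"type": "string", "minLength": 1},
          "terms": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "array",
              "items": [
                {"type": "string", "minLength": 1},
                {"$ref": "#/definitions/decimal"}
              ],
              "minItems": 2,
              "maxItems": 2
            }
          }
        }
      }
    },
    "metadata": {"type": "object"}
  }
}
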