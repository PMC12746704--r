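{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "acetalnet reaction network file",
  "version": "1.0",
  "type": "object",
  "required": ["units", "temperature_K", "references", "species", "steps"],
  "properties": {
    "schema_version": {"type": "string"},
    "units": {"enum": ["kJ/mol", "eV"]},
    "temperature_K": {"type": "number", "exclusiveMinimum": 0},
    "references": {
      "type": "array", "minItems": 4, "maxItems": 4,
      "items": {"type": "string"},
      "description": "ids of the sugar reference, HCHO, H2O, H3O+ (in order)"
    },
    "species": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "role", "stoich"],
        "properties": {
          "id": {"type": "string"},
          "role": {"enum": ["reference", "sugar_tautomer", "open_intermediate",
                            "protonated_intermediate", "monoacetal", "diacetal",
                            "transition_state", "small_molecule"]},
          "charge": {"type": "integer"},
          "stoich": {"type": "array", "minItems": 4, "maxItems": 4,
                     "items": {"type": "integer"},
                     "description": "(a, b, c, d): counts of sugar reference, HCHO, H2O, H3O+"},
          "energy_terms": {
            "type": "object", "required": ["E", "ZPE", "S"],
            "properties": {
              "E": {"type": "number", "description": "electronic energy, file units"},
              "ZPE": {"type": "number", "minimum": 0},
              "S": {"type": "number", "minimum": 0, "description": "entropy, J/(K mol), always"}
            }
          },
          "g_formation": {"type": "number"},
          "note": {"type": "string"}
        }
      }
    },
    "steps": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "from", "to", "delta_g"],
        "properties": {
          "id": {"type": "string"},
          "from": {"type": "string"},
          "to": {"type": "string"},
          "delta_g": {"type": "number"},
          "g_a": {"type": "number", "minimum": 0,
                  "description": "forward activation free energy; 0 = barrierless, absent = not computed"},
          "ts_id": {"type": "string"},
          "consumes": {"type": "object", "additionalProperties": {"type": "integer"}},
          "releases": {"type": "object", "additionalProperties": {"type": "integer"}},
          "reversible": {"type": "boolean"},
          "equilibrated": {"type": "boolean"},
          "tags": {"type": "array", "items": {"enum": ["1", "2", "3", "side"]}}
        }
      }
    }
  }
}
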