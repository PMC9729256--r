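{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "orthogem JSON model dialect",
  "description": "Direct serialization of a genome-scale metabolic model as read and written by read_gem()/write_gem(). Flux bounds are in mmol gCDW^-1 h^-1; stoichiometric coefficients are negative for substrates, positive for products; gpr is rule text over gene ids with 'and'/'or' and parentheses (empty string = no rule).",
  "type": "object",
  "required": ["id", "compartments", "metabolites", "reactions", "genes", "objective"],
  "properties": {
    "id": {"type": "string"},
    "compartments": {"type": "array", "items": {"type": "string"}},
    "metabolites": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "compartment"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "formula": {"type": "string", "pattern": "^([A-Z][a-z]?[0-9]*)+$"},
          "charge": {"type": "integer"},
          "compartment": {"type": "string"}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "lower_bound", "upper_bound", "stoichiometry"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "lower_bound": {"type": "number"},
          "upper_bound": {"type": "number"},
          "stoichiometry": {
            "type": "object",
            "additionalProperties": {"type": "number"}
          },
          "gpr": {"type": "string"},
          "ec": {"type": "array", "items": {"type": "string"}},
          "is_exchange": {"type": "boolean"},
          "notes": {"type": "string"}
        }
      }
    },
    "genes": {"type": "array", "items": {"type": "string"}},
    "objective": {"type": "string", "description": "biomass reaction id; empty string for none"}
  }
}
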