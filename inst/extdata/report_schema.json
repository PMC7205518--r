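{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "defenscan report",
  "type": "object",
  "required": ["schema_version", "label", "config"],
  "properties": {
    "schema_version": {"type": "string"},
    "label": {"type": "string"},
    "config": {"type": "object"},
    "defense": {
      "type": "object",
      "properties": {
        "n_defense_genes": {"type": "integer"},
        "n_assigned": {"type": "integer"},
        "n_ambiguous": {"type": "integer"},
        "per_system": {"type": "object"},
        "pct_defense_of_all_genes": {"type": "number"}
      }
    },
    "cas": {
      "type": "object",
      "properties": {
        "n_modules": {"type": "integer"},
        "n_classified": {"type": "integer"}
      }
    },
    "crispr": {
      "type": "object",
      "properties": {
        "n_arrays": {"type": "integer"},
        "n_spacers": {"type": "integer"},
        "majority_cutoff": {"type": "integer"}
      }
    },
    "match": {"type": "object"},
    "network": {"type": "object"}
  }
}
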