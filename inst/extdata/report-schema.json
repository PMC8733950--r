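{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cladediv divergence report",
  "type": "object",
  "required": ["clades", "tests", "samples", "provenance"],
  "properties": {
    "clades": {
      "type": "object",
      "required": ["a", "b"],
      "properties": {
        "a": {
          "type": "object",
          "required": ["n_leaves", "n_pruned_leaves", "sample_size",
                       "mean_length", "median_length"],
          "properties": {
            "n_leaves": { "type": "integer" },
            "n_species": { "type": "integer" },
            "n_pruned_leaves": { "type": "integer" },
            "sample_size": { "type": "integer" },
            "mean_length": { "type": "number" },
            "median_length": { "type": "number" }
          }
        },
        "b": {
          "type": "object",
          "required": ["n_leaves", "n_pruned_leaves", "sample_size",
                       "mean_length", "median_length"],
          "properties": {
            "n_leaves": { "type": "integer" },
            "n_species": { "type": "integer" },
            "n_pruned_leaves": { "type": "integer" },
            "sample_size": { "type": "integer" },
            "mean_length": { "type": "number" },
            "median_length": { "type": "number" }
          }
        }
      }
    },
    "tests": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name"],
        "properties": {
          "name": { "type": "string" },
          "statistic": { "type": "number" },
          "df": { "type": "number" },
          "p_value": { "type": "number" },
          "p_display": { "type": "string" },
          "n1": { "type": "integer" },
          "n2": { "type": "integer" },
          "method": { "type": "string" },
          "error": { "type": "string" }
        }
      }
    },
    "species": {
      "type": "object",
      "required": ["common", "unique_a", "unique_b", "relation"],
      "properties": {
        "common": { "type": "integer" },
        "unique_a": { "type": "integer" },
        "unique_b": { "type": "integer" },
        "relation": {
          "type": "string",
          "enum": ["A_superset", "B_superset", "equal", "overlap", "disjoint"]
        },
        "common_species": { "type": "array", "items": { "type": "string" } },
        "unique_a_species": { "type": "array", "items": { "type": "string" } },
        "unique_b_species": { "type": "array", "items": { "type": "string" } }
      }
    },
    "samples": {
      "type": "object",
      "required": ["a", "b"],
      "properties": {
        "a": { "type": "array", "items": { "type": "number" } },
        "b": { "type": "array", "items": { "type": "number" } }
      }
    },
    "provenance": {
      "type": "object",
      "required": ["tool", "version", "input_md5"],
      "properties": {
        "species_pattern": { "type": "string" },
        "unmatched_policy": { "type": "string" },
        "include_stem": { "type": "boolean" },
        "tool": { "type": "string" },
        "version": { "type": "string" },
        "input_md5": { "type": "string" }
      }
    }
  }
}
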