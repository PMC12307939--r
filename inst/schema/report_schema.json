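{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "bioecon pipeline report",
  "type": "object",
  "required": ["provenance", "impacts", "projections", "cba", "rounding"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "table_source", "config", "config_hash"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "table_source": {"type": "string"},
        "seed": {"type": "integer"},
        "config": {"type": "object"},
        "config_hash": {"type": "string"}
      }
    },
    "impacts": {
      "type": "object",
      "required": ["base", "adjusted", "incremental", "labels", "closure_type"],
      "properties": {
        "base": {"type": "object"},
        "adjusted": {"type": "object"},
        "incremental": {"type": "array"},
        "labels": {"type": "array"},
        "closure_type": {"type": "string"}
      }
    },
    "projections": {
      "type": "object",
      "required": ["b", "g", "horizons", "cumulative_totals"],
      "properties": {
        "b": {"type": "number"},
        "g": {"type": "number"},
        "horizons": {"type": "array"},
        "cumulative_totals": {"type": "array"}
      }
    },
    "cba": {
      "type": "object",
      "required": ["total_benefits", "total_costs", "pv_benefits", "pv_costs", "npv", "bcr", "rate", "T"],
      "properties": {
        "total_benefits": {"type": "number"},
        "total_costs": {"type": "number"},
        "pv_benefits": {"type": "number"},
        "pv_costs": {"type": "number"},
        "npv": {"type": "number"},
        "bcr": {"type": "number"},
        "rate": {"type": "number"},
        "T": {"type": "integer"}
      }
    },
    "rounding": {
      "type": "object",
      "required": ["musd_digits", "share_digits"],
      "properties": {
        "musd_digits": {"type": "integer"},
        "share_digits": {"type": "integer"}
      }
    }
  }
}
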