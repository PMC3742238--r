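{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "SpecBind analysis report",
  "type": "object",
  "required": ["schema_version", "provenance", "quenching", "mechanism", "thermo"],
  "properties": {
    "schema_version": {"type": "string"},
    "provenance": {
      "type": "object",
      "required": ["package", "package_version", "seed", "config_hash"],
      "properties": {
        "package": {"type": "string"},
        "package_version": {"type": "string"},
        "seed": {"type": "integer"},
        "config_hash": {"type": "string"},
        "config": {"type": "object"}
      }
    },
    "quenching": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["T_K", "stern_volmer", "modified_sv", "double_log"],
        "properties": {
          "T_K": {"type": "number"},
          "stern_volmer": {
            "type": "object",
            "required": ["Ksv_per_M", "kq_per_M_s", "tau0_s", "intercept", "r"]
          },
          "modified_sv": {
            "type": "object",
            "required": ["Ka_per_M", "fa", "r", "valid"]
          },
          "double_log": {
            "type": "object",
            "required": ["Kb_per_M", "n_sites", "r"]
          }
        }
      }
    },
    "mechanism": {
      "type": "object",
      "required": ["mechanism", "rationale"],
      "properties": {
        "mechanism": {"enum": ["static", "dynamic", "indeterminate"]},
        "rationale": {"type": "string"}
      }
    },
    "thermo": {
      "type": "object",
      "required": ["van_t_hoff", "gibbs_kJ_mol", "forces"],
      "properties": {
        "van_t_hoff": {
          "type": "object",
          "required": ["dH_kJ_mol", "dS_J_molK", "r", "source"]
        },
        "gibbs_kJ_mol": {"type": "object"},
        "forces": {"type": "array", "items": {"type": "string"}},
        "narrative": {"type": "string"}
      }
    },
    "fret": {
      "type": "object",
      "required": ["J_cm3_L_mol", "R0_nm", "E", "r_nm", "flags"]
    },
    "cd": {
      "type": "object",
      "required": ["table"],
      "properties": {
        "table": {"type": "array"},
        "monotone_decrease": {"type": "boolean"}
      }
    },
    "synchronous": {"type": "object"}
  }
}
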