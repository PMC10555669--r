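{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "GWAS summary-statistics QC report",
  "type": "object",
  "required": ["metadata", "filters", "flags", "slopes", "correlations",
               "classifications", "disposition"],
  "properties": {
    "metadata": {"type": "object"},
    "filters": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rule", "detail"],
        "properties": {
          "rule": {"enum": ["duplicate", "triallelic", "missing_beta_se",
                            "unmappable_rsid", "low_mac"]},
          "rsid": {"type": ["string", "null"]},
          "detail": {"type": "string"}
        }
      }
    },
    "flags": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["check", "rsid", "level", "reason"],
        "properties": {
          "check": {"type": "string"},
          "rsid": {"type": "string"},
          "level": {"enum": ["none", "moderate", "high"]},
          "reason": {"type": "string"}
        }
      }
    },
    "slopes": {"type": "object"},
    "correlations": {"type": "object"},
    "classifications": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["check", "classification", "n_compared"],
        "properties": {
          "classification": {"enum": ["consistent", "systematic_flip",
                                      "maf_coded", "ambiguous"]}
        }
      }
    },
    "pz": {"type": "object"},
    "instrument": {"type": "object"},
    "recommendations": {"type": "array", "items": {"type": "string"}},
    "disposition": {"enum": ["pass", "investigate", "exclude-recommended"]}
  }
}
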