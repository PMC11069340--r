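{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "rhizoscreen run report",
  "type": "object",
  "required": ["package_version", "config", "n_genes", "n_upregulated",
               "n_candidates", "hotspots"],
  "properties": {
    "package_version": {"type": "string"},
    "config": {"type": "object"},
    "n_genes": {"type": "integer", "minimum": 0},
    "n_upregulated": {"type": "integer", "minimum": 0},
    "n_candidates": {"type": "integer", "minimum": 0},
    "hotspots": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["replicon_id", "start_rank", "end_rank", "locus_ids",
                     "n_candidates", "span", "score"],
        "properties": {
          "replicon_id": {"type": "string"},
          "start_rank": {"type": "integer", "minimum": 1},
          "end_rank": {"type": "integer", "minimum": 1},
          "locus_ids": {"type": "array", "items": {"type": "string"}},
          "n_candidates": {"type": "integer", "minimum": 1},
          "span": {"type": "integer", "minimum": 1},
          "score": {"type": "number"}
        }
      }
    },
    "enrichment": {
      "type": ["object", "null"],
      "properties": {
        "table": {"type": "array"},
        "odds_ratio": {"type": ["number", "string"]},
        "p_two_sided": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "growth": {"type": "object"},
    "annotations": {"type": ["array", "object"]}
  }
}
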