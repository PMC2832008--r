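{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "noduleWaves run report",
  "type": "object",
  "required": [
    "software", "seed", "config", "normalization", "de", "profiles",
    "sample_clusters", "enrichment", "differentiation", "classification"
  ],
  "properties": {
    "software": {"type": "object"},
    "seed": {"type": "integer"},
    "config": {"type": "object"},
    "normalization": {"type": "object"},
    "de": {"type": "object"},
    "profiles": {"type": "object"},
    "sample_clusters": {"type": "object"},
    "enrichment": {},
    "differentiation": {"type": "object"},
    "classification": {"type": "object"}
  }
}
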