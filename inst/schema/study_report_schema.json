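{
  "title": "dgrtools study report",
  "schema_version": "1.0",
  "required": {
    "schema_version": "string",
    "software": "string",
    "n_sessions": "number",
    "maroc_mgdl_min": "number",
    "pooled": "object",
    "sessions": "array",
    "config": "object"
  },
  "pooled_required": ["n", "counts", "fractions", "compliant"]
}
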