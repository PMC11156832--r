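{
  "title": "angioqa similarity report",
  "required": {
    "provenance": "object",
    "comparisons": "array"
  },
  "provenance_fields": {
    "package": "string",
    "version": "string",
    "config_hash": "string",
    "global_seed": "integer",
    "seed_derivation": "string"
  },
  "comparison_fields": {
    "rotation_deg": "number",
    "cwssi": "number",
    "preprocessing_log": "array"
  }
}
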