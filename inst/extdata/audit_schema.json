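{
  "required": ["combine_policy", "stages", "dropped_genes", "ba", "wa"],
  "numeric_fields": {"stage_counts": "stages"}
}
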