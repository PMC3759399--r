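{
  "said": "485290",
  "comment": "TDP1 inhibitors: all compounds active in the confirmation screen; inactives from the primary screen.",
  "inactive_source": "485290",
  "expression": {"assay": "489007", "set": "active"}
}
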