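{
  "said": "435008",
  "comment": "Orexin1 receptor antagonists: union of the two most refined validation screens; inactives from the primary screen.",
  "inactive_source": "485270",
  "expression": {
    "op": "union",
    "args": [
      {"assay": "504701", "set": "active"},
      {"assay": "504699", "set": "active"}
    ]
  }
}
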