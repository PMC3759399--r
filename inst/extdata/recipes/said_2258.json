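{
  "said": "2258",
  "comment": "KCNQ2 potentiators: confirmatory actives minus the three counter screens; inactives from the primary screen.",
  "inactive_source": "2239",
  "expression": {
    "op": "subtract",
    "args": [
      {"assay": "2287", "set": "active"},
      {"assay": "2282", "set": "active"},
      {"assay": "2283", "set": "active"},
      {"assay": "2558", "set": "active"}
    ]
  }
}
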