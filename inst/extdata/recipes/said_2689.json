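{
  "said": "2689",
  "comment": "STK33 inhibitors: counter-screen actives minus PKA-selectivity actives; inactives from the primary screen.",
  "inactive_source": "2661",
  "expression": {
    "op": "subtract",
    "args": [
      {"assay": "2821", "set": "active"},
      {"assay": "504583", "set": "active"}
    ]
  }
}
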