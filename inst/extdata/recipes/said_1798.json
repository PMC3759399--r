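{
  "said": "1798",
  "comment": "M1 muscarinic positive allosteric modulators: confirmed agonist actives minus M4 cross-actives; inactives from the primary screen.",
  "inactive_source": "626",
  "expression": {
    "op": "subtract",
    "args": [
      {"assay": "1488", "set": "active"},
      {"assay": "1741", "set": "active"}
    ]
  }
}
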