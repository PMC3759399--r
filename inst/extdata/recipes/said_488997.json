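{
  "said": "488997",
  "comment": "Choline transporter inhibitors: overlap of the three validation screens minus non-specific hits and reconfirmation inactives; inactives from the primary screen.",
  "inactive_source": "488975",
  "expression": {
    "op": "subtract",
    "args": [
      {
        "op": "intersect",
        "args": [
          {"assay": "493221", "set": "active"},
          {"assay": "504840", "set": "active"},
          {"assay": "588401", "set": "active"}
        ]
      },
      {"assay": "493222", "set": "active"},
      {"assay": "602208", "set": "inactive"}
    ]
  }
}
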