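{
  "said": "1843",
  "comment": "Kir2.1 inhibitors: compounds active in both validation screens minus the four counter screens; inactives from the primary screen.",
  "inactive_source": "1672",
  "expression": {
    "op": "subtract",
    "args": [
      {
        "op": "intersect",
        "args": [
          {"assay": "2032", "set": "active"},
          {"assay": "463252", "set": "active"}
        ]
      },
      {"assay": "2105", "set": "active"},
      {"assay": "2345", "set": "active"},
      {"assay": "2236", "set": "active"},
      {"assay": "2329", "set": "active"}
    ]
  }
}
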