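{
  "A*34:AB": ["A*34:01", "A*34:02"],
  "A*02:CD": ["A*02:01", "A*02:05", "A*02:06"],
  "B*15:EF": ["B*15:01", "B*15:03"],
  "DRB1*13:GH": ["DRB1*13:01", "DRB1*13:02"]
}
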