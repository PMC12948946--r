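{
  "grain_bases": ["wheat", "spelt", "rye", "mixture"],
  "milling_grades": ["wholemeal", "semi-wholemeal", "endosperm"],
  "unspecified_grade": "unspecified"
}
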