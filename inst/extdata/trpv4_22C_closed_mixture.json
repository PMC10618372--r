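{
  "class": "closed",
  "taus": [0.58, 5.26, 71.22],
  "areas": [0.58, 0.3, 0.12],
  "temperature": 22
}
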