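{
  "mapping": {
    "activation": 1,
    "increases": 1,
    "->": 1,
    "inhibition": -1,
    "decreases": -1,
    "-|": -1,
    "association": 1
  },
  "default": 1
}
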