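{
  "rate_constant": {
    "v12": 8,
    "v14": 2,
    "v23": 3,
    "v3out": 5,
    "v4out": 6,
    "vin": 12
  },
  "kinetic_order": {
    "v12:X1": 0.5,
    "v14:X1": 0.5,
    "v23:X2": 0.75,
    "v3out:X3": 0.5,
    "v3out:X4": 0.2,
    "v4out:X4": 0.8,
    "vin:X3": -0.8
  }
}
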