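{
  "X1": "0.9053",
  "X2": "0.8302",
  "X3": "0.8",
  "X4": "0.0054",
  "X5": "4.0172",
  "X6": "5000",
  "X7": "0.011",
  "X8": "1000",
  "X9": "7.5",
  "X10": "0.005",
  "X11": "0.9",
  "X12": "0.02",
  "X13": "0"
}
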