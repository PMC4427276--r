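{
  "X1": "1.1121",
  "X2": "1.0301",
  "X3": "1.1874",
  "X4": "1.1707",
  "X5": "0.9116",
  "Y1": "49.73",
  "Y2": "45.8097",
  "Y3": "48.8933",
  "Y4": "48.13",
  "Y5": "47.85",
  "Y6": "48.9782",
  "Y7": "1",
  "Y8": "1"
}
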