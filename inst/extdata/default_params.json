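{
  "t_th": 24.5,
  "t_com": 25.5,
  "d_th": -1,
  "d_com": 6,
  "positions": [0.2, 0.4, 0.6, 0.8]
}
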