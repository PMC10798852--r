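{
  "analytic": {"r_min": 0.75, "c_max": 0.1},
  "visual": {"r_min": 0.3, "c_max": 0.06},
  "olfactory": {"r_min": 0.4, "c_max": 0.1}
}
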