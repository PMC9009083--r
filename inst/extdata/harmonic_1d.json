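{
  "coefficients": [0, 12.5],
  "range": [-5, 5],
  "comment": "V(x) = x^2/2 expressed in the scaled coordinate u = x/5"
}
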