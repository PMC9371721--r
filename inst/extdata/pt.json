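{
  "name": "pt",
  "dD_um": 20,
  "channels": [
    {
      "i0_A_per_m2": 3e-06,
      "n_rds": 1,
      "n_stoich": 4,
      "alpha_c": 0.5
    }
  ]
}
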