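{
  "name": "au",
  "dD_um": 50,
  "channels": [
    {
      "i0_A_per_m2": 2e-08,
      "n_rds": 1,
      "n_stoich": 4,
      "alpha_c": 0.5
    },
    {
      "i0_A_per_m2": 8e-07,
      "n_rds": 0.7,
      "n_stoich": 2,
      "alpha_c": 0.5
    }
  ]
}
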