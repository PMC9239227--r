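{
  "mu_specialist": 0.1,
  "carrying_capacity": 10000000000,
  "transfer_fraction": 0.1,
  "initial_specialist": 100000000,
  "initial_generalist": 10000,
  "substrate_order": ["soil", "digestate"],
  "death_rate": 0.03046875,
  "duration": 140,
  "critical_ratio": 0.259765625
}
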