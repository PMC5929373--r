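variant: wild_type
substrate: (R,R)-1a
values:
  kcat: 4.7
  kcat_se: 0.7
  Km: 490.0
  Km_se: 100.0
  kcat_over_Km: 9.7
  kcat_over_Km_se: 2.0
  sum_k5_km5: 8.1
  sum_k5_km5_se: 3.0
regioselectivity: 55% C1
provenance: 'StEH1 wild type with (R,R)-1a: published steady-state and stopped-flow
  kinetic parameters'
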