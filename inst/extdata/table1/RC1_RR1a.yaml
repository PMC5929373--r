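variant: R-C1
substrate: (R,R)-1a
values:
  kcat: 25.0
  kcat_se: 4.0
  Km: 3300.0
  Km_se: 10.0
  kcat_over_Km: 7.7
  kcat_over_Km_se: 0.2
  sum_k5_km5: 48.0
  sum_k5_km5_se: 70.0
regioselectivity: 66% C1
provenance: 'StEH1 R-C1 with (R,R)-1a: published steady-state and stopped-flow kinetic
  parameters'
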