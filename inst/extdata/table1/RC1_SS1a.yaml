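variant: R-C1
substrate: (S,S)-1a
values:
  kcat: 65.0
  kcat_se: 2.0
  Km: 110.0
  Km_se: 10.0
  kcat_over_Km: 560.0
  kcat_over_Km_se: 40.0
  K_S: 1600.0
  K_S_se: 900.0
  k2: 2100.0
  k2_se: 600.0
  k_m2: 240.0
  k_m2_se: 60.0
  k3: 75.0
  k3_se: 30.0
  sum_k5_km5: 44.0
  sum_k5_km5_se: 50.0
regioselectivity: 99% C1
notes: k-2 and k3 calculated from the steady-state kcat expression and the measured
  sum k-2 + k3
provenance: 'StEH1 R-C1 with (S,S)-1a: published steady-state and stopped-flow kinetic
  parameters'
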