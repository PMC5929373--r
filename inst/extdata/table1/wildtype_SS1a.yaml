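variant: wild_type
substrate: (S,S)-1a
values:
  kcat: 63.0
  kcat_se: 3.0
  Km: 77.0
  Km_se: 10.0
  kcat_over_Km: 820.0
  kcat_over_Km_se: 100.0
  K_S: 470.0
  K_S_se: 100.0
  k2: 370.0
  k2_se: 20.0
  k_m2: 170.0
  k_m2_se: 20.0
  k3: 110.0
  k3_se: 10.0
  sum_k5_km5: 32.0
  sum_k5_km5_se: 2.0
regioselectivity: 99% C1
notes: k-2 and k3 calculated from the steady-state kcat expression and the measured
  sum k-2 + k3
provenance: 'StEH1 wild type with (S,S)-1a: published steady-state and stopped-flow
  kinetic parameters'
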