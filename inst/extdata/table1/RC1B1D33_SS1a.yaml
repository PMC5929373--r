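variant: R-C1B1D33
substrate: (S,S)-1a
values:
  kcat: 79.0
  kcat_se: 5.0
  Km: 410.0
  Km_se: 40.0
  kcat_over_Km: 190.0
  kcat_over_Km_se: 20.0
  K_S: 6500.0
  K_S_se: 6000.0
  k2: 2600.0
  k2_se: 2000.0
  k_m2: 74.0
  k_m2_se: 90.0
  k3: 84.0
  k3_se: 90.0
regioselectivity: 99% C1
notes: k-2 and k3 calculated from the steady-state kcat expression and the measured
  sum k-2 + k3
provenance: 'StEH1 R-C1B1D33 with (S,S)-1a: published steady-state and stopped-flow
  kinetic parameters'
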