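variant: R-C1B1
substrate: (S,S)-1a
values:
  kcat: 31.0
  kcat_se: 1.0
  Km: 240.0
  Km_se: 20.0
  kcat_over_Km: 130.0
  kcat_over_Km_se: 6.0
  K_S: 2700.0
  K_S_se: 2000.0
  k2: 1400.0
  k2_se: 800.0
  k_m2: 10.0
  k_m2_se: 30.0
  k3: 32.0
  k3_se: 20.0
regioselectivity: 99% C1
notes: k-2 and k3 calculated from the steady-state kcat expression and the measured
  sum k-2 + k3
provenance: 'StEH1 R-C1B1 with (S,S)-1a: published steady-state and stopped-flow kinetic
  parameters'
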