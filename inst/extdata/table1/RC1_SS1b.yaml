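variant: R-C1
substrate: (S,S)-1b
values:
  kcat: 4.4
  kcat_se: 0.09
  Km: 1.3
  Km_se: 0.09
  kcat_over_Km: 3300.0
  kcat_over_Km_se: 20.0
  K_S: 16.0
  K_S_se: 5.0
  k2: 120.0
  k2_se: 9.0
  k_m2: 4.2
  k_m2_se: 6.0
  k3: 5.4
  k3_se: 0.01
regioselectivity: Meso product
notes: k3 determined in a single-turnover experiment
provenance: 'StEH1 R-C1 with (S,S)-1b: published steady-state and stopped-flow kinetic
  parameters'
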