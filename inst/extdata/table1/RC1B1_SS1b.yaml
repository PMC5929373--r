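variant: R-C1B1
substrate: (S,S)-1b
values:
  kcat: 4.0
  kcat_se: 0.09
  Km: 16.0
  Km_se: 0.9
  kcat_over_Km: 250.0
  kcat_over_Km_se: 0.09
  K_S: 21.0
  K_S_se: 10.0
  k2: 8.9
  k2_se: 1.0
  k_m2: 5.1
  k_m2_se: 0.08
  k3: 3.0
  k3_se: 0.01
regioselectivity: Meso product
notes: k3 determined in a single-turnover experiment
provenance: 'StEH1 R-C1B1 with (S,S)-1b: published steady-state and stopped-flow kinetic
  parameters'
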