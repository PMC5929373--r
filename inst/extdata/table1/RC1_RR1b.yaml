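variant: R-C1
substrate: (R,R)-1b
values:
  kcat: 12.0
  kcat_se: 0.5
  Km: 20.0
  Km_se: 2.0
  kcat_over_Km: 610.0
  kcat_over_Km_se: 40.0
  K_S: 13.0
  K_S_se: 17.0
  k2: 85.0
  k2_se: 3.0
  k_m2: 22.0
  k_m2_se: 40.0
  k3: 28.0
  k3_se: 0.2
regioselectivity: Meso product
notes: k3 determined in a single-turnover experiment
provenance: 'StEH1 R-C1 with (R,R)-1b: published steady-state and stopped-flow kinetic
  parameters'
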