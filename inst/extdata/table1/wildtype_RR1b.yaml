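variant: wild_type
substrate: (R,R)-1b
values:
  kcat: 17.0
  kcat_se: 0.5
  Km: 16.0
  Km_se: 1.0
  kcat_over_Km: 1100.0
  kcat_over_Km_se: 50.0
  K_S: 7.8
  K_S_se: 13.0
  k2: 180.0
  k2_se: 100.0
  k_m2: 13.0
  k_m2_se: 10.0
  k3: 42.0
  k3_se: 0.2
regioselectivity: Meso product
notes: k3 determined in a single-turnover experiment
provenance: 'StEH1 wild type with (R,R)-1b: published steady-state and stopped-flow
  kinetic parameters'
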