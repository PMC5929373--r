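variant: wild_type
substrate: (S,S)-1b
values:
  kcat: 4.0
  kcat_se: 0.06
  Km: 1.0
  Km_se: 0.08
  kcat_over_Km: 3900.0
  kcat_over_Km_se: 200.0
  K_S: 5.5
  K_S_se: 0.9
  k2: 23.0
  k2_se: 0.7
  k_m2: 4.5
  k_m2_se: 0.8
  k3: 3.9
  k3_se: 0.005
regioselectivity: Meso product
notes: k3 determined in a single-turnover experiment
provenance: 'StEH1 wild type with (S,S)-1b: published steady-state and stopped-flow
  kinetic parameters'
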