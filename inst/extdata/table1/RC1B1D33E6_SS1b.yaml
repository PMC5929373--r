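variant: R-C1B1D33E6
substrate: (S,S)-1b
values:
  kcat: 0.42
  kcat_se: 0.09
  Km: 110.0
  Km_se: 30.0
  kcat_over_Km: 3.1
  kcat_over_Km_se: 0.2
regioselectivity: Meso product
notes: alkylation too fast to resolve within the instrument dead time
provenance: 'StEH1 R-C1B1D33E6 with (S,S)-1b: published steady-state and stopped-flow
  kinetic parameters'
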