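variant: R-C1B1D33
substrate: (S,S)-1b
values:
  kcat: 12.0
  kcat_se: 0.7
  Km: 65.0
  Km_se: 6.0
  kcat_over_Km: 180.0
  kcat_over_Km_se: 6.0
regioselectivity: Meso product
notes: alkylation too fast to resolve within the instrument dead time
provenance: 'StEH1 R-C1B1D33 with (S,S)-1b: published steady-state and stopped-flow
  kinetic parameters'
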