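variant: R-C1B1D33
substrate: (R,R)-1b
values:
  kcat: 0.38
  kcat_se: 0.09
  Km: 190.0
  Km_se: 60.0
  kcat_over_Km: 2.0
  kcat_over_Km_se: 0.1
regioselectivity: Meso product
provenance: 'StEH1 R-C1B1D33 with (R,R)-1b: published steady-state and stopped-flow
  kinetic parameters'
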