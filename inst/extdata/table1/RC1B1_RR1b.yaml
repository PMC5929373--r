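variant: R-C1B1
substrate: (R,R)-1b
values:
  kcat: 0.51
  kcat_se: 0.09
  Km: 170.0
  Km_se: 40.0
  kcat_over_Km: 3.1
  kcat_over_Km_se: 0.1
regioselectivity: Meso product
provenance: 'StEH1 R-C1B1 with (R,R)-1b: published steady-state and stopped-flow kinetic
  parameters'
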