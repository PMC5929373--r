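variant: R-C1B1
substrate: (R,R)-1a
values:
  kcat: 0.92
  kcat_se: 0.4
  Km: 3400.0
  Km_se: 200.0
  kcat_over_Km: 0.26
  kcat_over_Km_se: 0.01
regioselectivity: 89% C2
provenance: 'StEH1 R-C1B1 with (R,R)-1a: published steady-state and stopped-flow kinetic
  parameters'
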