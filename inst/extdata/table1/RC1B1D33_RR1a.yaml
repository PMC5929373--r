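variant: R-C1B1D33
substrate: (R,R)-1a
values:
  kcat_over_Km: 0.25
  kcat_over_Km_se: 0.01
regioselectivity: 91% C2
notes: kcat and Km not saturating
provenance: 'StEH1 R-C1B1D33 with (R,R)-1a: published steady-state and stopped-flow
  kinetic parameters'
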