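variant: R-C1B1D33E6
substrate: (R,R)-1b
values: []
regioselectivity: Meso product
notes: only an upper bound on kcat/Km reported (< 0.1 s^-1 mM^-1)
provenance: 'StEH1 R-C1B1D33E6 with (R,R)-1b: published steady-state and stopped-flow
  kinetic parameters'
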