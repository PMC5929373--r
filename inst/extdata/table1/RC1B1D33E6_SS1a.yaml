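variant: R-C1B1D33E6
substrate: (S,S)-1a
values:
  kcat_over_Km: 10.0
  kcat_over_Km_se: 0.2
regioselectivity: 99% C1
notes: kcat and Km not saturating
provenance: 'StEH1 R-C1B1D33E6 with (S,S)-1a: published steady-state and stopped-flow
  kinetic parameters'
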