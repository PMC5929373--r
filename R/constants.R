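# Physical constants (CODATA 2018 exact values).
# Units fixed package-wide: s, s^-1, uM, kcal mol^-1, K.

.kB <- 1.380649e-23        # Boltzmann constant, J K^-1
.h  <- 6.62607015e-34      # Planck constant, J s
.R_KCAL <- 1.98720425e-3   # gas constant, kcal mol^-1 K^-1

#: default assay temperature, 30 degrees C
.T_DEFAULT <- 303.15
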