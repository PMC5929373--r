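# Shared fixtures and closed-form oracles used across the test files.

# hyperbolic concentration dependence of the transient rate for the
# linear scheme under rapid-equilibrium binding
eq4_kobs <- function(S, k2, K_S, intercept) k2 * S / (K_S + S) + intercept

# slow relaxation of the saturated ES <-> EA -> E + P subsystem
# (single-turnover recovery oracle), from the 2x2 characteristic
# polynomial
saturated_slow_eigen <- function(k2, k_m2, k3) {
  tr <- k2 + k_m2 + k3
  (tr - sqrt(tr^2 - 4 * k2 * k3)) / 2
}

wt_ssa_rates <- function(...) {
  rate_set(k2 = 370, k_m2 = 170, k3 = 110, K_S = 470, ...)
}

wt_ssa_fixture_rates <- function() {
  as_rate_set(table1_fixture("wild_type", "(S,S)-1a"))
}

# frequency factor of transition-state theory
.kB_T_over_h <- function(T_K) 1.380649e-23 * T_K / 6.62607015e-34
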