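#' Relaxation rates of the enzyme subsystem at fixed substrate
#'
#' Linearizes the branched scheme in the pseudo-first-order regime
#' (free substrate clamped at `S`) and returns the eigenvalue magnitudes
#' of the six-species enzyme system (E, E', ES, E'S, and the two
#' alkylenzymes). These are the relaxation rates an ideal stopped-flow
#' experiment observes; the slowest nonzero one corresponds to the
#' transient `k_obs` of an exponential fit. One eigenvalue is always 0
#' (enzyme conservation); all others have non-positive real parts.
#'
#' @param rates a [rate_set()].
#' @param S clamped free-substrate concentration (uM), >= 0.
#' @return numeric vector of eigenvalue magnitudes (s^-1), sorted
#'   decreasing; magnitudes below 1e-9 times the largest are reported
#'   as exactly 0.
#' @examples
#' rs <- rate_set(k2 = 370, k_m2 = 170, k3 = 110, K_S = 470)
#' relaxation_rates(rs, 470)
#' @export
relaxation_rates <- function(rates, S) {
  stopifnot(inherits(rates, "rate_set"))
  check_scalar(S, "S", nonneg = TRUE)
  koff <- rates$kon * rates$K_S
  koffp <- rates$kon * rates$K_S_prime
  konS <- rates$kon * S
  # state order: E, Ep, ES, EpS, EA, EpA
  M <- matrix(0, 6, 6)
  M[1, ] <- c(-konS - rates$k0, rates$k_m0, koff, 0, rates$k3, 0)
  M[2, ] <- c(rates$k0, -konS - rates$k_m0, 0, koffp, 0, rates$k3_prime)
  M[3, ] <- c(konS, 0, -koff - rates$k5 - rates$k2, rates$k_m5,
              rates$k_m2, 0)
  M[4, ] <- c(0, konS, rates$k5, -koffp - rates$k_m5 - rates$k2_prime,
              0, rates$k_m2_prime)
  M[5, ] <- c(0, 0, rates$k2, 0, -rates$k_m2 - rates$k3, 0)
  M[6, ] <- c(0, 0, 0, rates$k2_prime, 0,
              -rates$k_m2_prime - rates$k3_prime)
  ev <- eigen(M, only.values = TRUE)$values
  mags <- Mod(ev)
  if (max(mags) > 0) mags[mags < 1e-9 * max(mags)] <- 0
  sort(mags, decreasing = TRUE)
}
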