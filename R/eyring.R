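#' Eyring conversion between rate constants and activation free energies
#'
#' Transition-state theory with transmission coefficient 1:
#' \deqn{k = \frac{k_B T}{h} e^{-\Delta G^\ddagger / RT}
#'  \quad\Longleftrightarrow\quad
#'  \Delta G^\ddagger = RT \ln\frac{k_B T}{h\,k}.}
#' `eyring_rate` is the exact inverse of `eyring_barrier`. Uses
#' R = 1.98720425e-3 kcal mol^-1 K^-1 and the exact SI values of kB and h.
#'
#' @param k first-order rate constant (s^-1), > 0. Vectorized.
#' @param T_K absolute temperature (K), > 0.
#' @return `eyring_barrier`: activation free energy in kcal mol^-1;
#'   `eyring_rate`: rate constant in s^-1.
#' @examples
#' eyring_barrier(370, 303.15)   # ~14.2 kcal/mol
#' eyring_rate(14.2, 303.15)     # ~3.7e2 s^-1
#' @export
eyring_barrier <- function(k, T_K = 303.15) {
  check_scalar(T_K, "T_K", positive = TRUE)
  if (!is.numeric(k) || any(!is.finite(k)))
    stop("'k' must be finite numeric", call. = FALSE)
  if (any(k <= 0)) stop("'k' must be > 0", call. = FALSE)
  .R_KCAL * T_K * log(.kB * T_K / (.h * k))
}

#' @rdname eyring_barrier
#' @param dG activation free energy (kcal mol^-1). Vectorized.
#' @export
eyring_rate <- function(dG, T_K = 303.15) {
  check_scalar(T_K, "T_K", positive = TRUE)
  if (!is.numeric(dG) || any(!is.finite(dG)))
    stop("'dG' must be finite numeric", call. = FALSE)
  .kB * T_K / .h * exp(-dG / (.R_KCAL * T_K))
}
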