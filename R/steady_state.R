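#' Steady-state parameters of the reduced linear scheme
#'
#' Analytic steady-state turnover number and Michaelis constant for the
#' linear three-step mechanism E + S <-> ES <-> E-alkyl -> E + P with
#' rapid-equilibrium binding (dissociation constant K_S):
#' \deqn{k_{cat} = \frac{k_2 k_3}{k_2 + k_{-2} + k_3}, \qquad
#'       K_m = K_S \frac{k_{-2} + k_3}{k_2 + k_{-2} + k_3}.}
#'
#' @param k2 alkylation rate constant (s^-1), > 0.
#' @param k_m2 de-alkylation rate constant (s^-1), >= 0.
#' @param k3 hydrolysis rate constant (s^-1), > 0.
#' @param K_S substrate dissociation constant (uM), > 0.
#' @return an object of class `steady_state_params` with fields `kcat`
#'   (s^-1), `Km` (uM) and `kcat_over_Km` (s^-1 mM^-1).
#' @examples
#' steady_state_params(k2 = 370, k_m2 = 170, k3 = 110, K_S = 470)
#' @export
steady_state_params <- function(k2, k_m2, k3, K_S) {
  check_scalar(k2, "k2", positive = TRUE)
  check_scalar(k_m2, "k_m2", nonneg = TRUE)
  check_scalar(k3, "k3", positive = TRUE)
  check_scalar(K_S, "K_S", positive = TRUE)
  denom <- k2 + k_m2 + k3
  kcat <- k2 * k3 / denom
  Km <- K_S * (k_m2 + k3) / denom
  structure(list(kcat = kcat, Km = Km,
                 kcat_over_Km = kcat / Km * 1000),
            class = "steady_state_params")
}

#' @export
print.steady_state_params <- function(x, ...) {
  cat(sprintf("kcat = %.4g s^-1, Km = %.4g uM, kcat/Km = %.4g s^-1 mM^-1\n",
              x$kcat, x$Km, x$kcat_over_Km))
  invisible(x)
}
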