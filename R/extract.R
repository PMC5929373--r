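#' Microscopic rate constants from transient and steady-state data
#'
#' Inverts the steady-state expression of the reduced linear scheme to
#' split the transient intercept \eqn{k_{-2} + k_3} (the S -> 0 limit of
#' the hyperbolic k_obs dependence) into its components, using the
#' independently measured turnover number:
#' \deqn{k_3 = k_{cat}\,\frac{k_2 + (k_{-2}+k_3)}{k_2}, \qquad
#'       k_{-2} = (k_{-2}+k_3) - k_3.}
#' By construction `steady_state_params(k2, k_m2, k3, K_S)$kcat`
#' reproduces the input `kcat` exactly. Standard errors are propagated
#' to first order (delta method) from the input standard errors,
#' treating k2, the sum and kcat as independent estimates.
#'
#' An implied negative k-2 (k3 greater than the measured sum) is
#' reported as-is and flagged, never clipped.
#'
#' @param k2 alkylation rate constant (s^-1), > 0.
#' @param K_S substrate dissociation constant (uM).
#' @param sum_km2_k3 the transient intercept k-2 + k3 (s^-1), > 0.
#' @param kcat steady-state turnover number (s^-1), > 0.
#' @param se_k2,se_K_S,se_sum,se_kcat standard errors of the inputs
#'   (optional).
#' @param sum_k5_km5,se_sum_k5_km5 optional Michaelis-complex
#'   interconversion rate sum from a decreasing k_obs dependence,
#'   carried through for reporting.
#' @return an object of class `micro_rates` with the central values
#'   `k2`, `K_S`, `k_m2`, `k3`, `sum_km2_k3`, optional `sum_k5_km5`,
#'   their standard errors in `se`, and `flags`.
#' @examples
#' extract_micro_rates(k2 = 370, K_S = 470, sum_km2_k3 = 280, kcat = 63)
#' @export
extract_micro_rates <- function(k2, K_S, sum_km2_k3, kcat,
                                se_k2 = NA_real_, se_K_S = NA_real_,
                                se_sum = NA_real_, se_kcat = NA_real_,
                                sum_k5_km5 = NULL,
                                se_sum_k5_km5 = NA_real_) {
  check_scalar(k2, "k2", positive = TRUE)
  check_scalar(K_S, "K_S", positive = TRUE)
  check_scalar(sum_km2_k3, "sum_km2_k3", positive = TRUE)
  check_scalar(kcat, "kcat", positive = TRUE)

  k3 <- kcat * (k2 + sum_km2_k3) / k2
  k_m2 <- sum_km2_k3 - k3

  # delta method over independent (k2, sum, kcat)
  g_k3 <- c(k2 = -kcat * sum_km2_k3 / k2^2,
            s = kcat / k2,
            kc = (k2 + sum_km2_k3) / k2)
  g_km2 <- c(k2 = kcat * sum_km2_k3 / k2^2,
             s = 1 - kcat / k2,
             kc = -(k2 + sum_km2_k3) / k2)
  vin <- c(k2 = se_k2^2, s = se_sum^2, kc = se_kcat^2)
  se_k3 <- sqrt(sum(g_k3^2 * vin))
  se_km2 <- sqrt(sum(g_km2^2 * vin))

  flags <- character(0)
  if (k_m2 < 0) flags <- c(flags, "implied_negative_k_m2")

  structure(list(k2 = k2, K_S = K_S, sum_km2_k3 = sum_km2_k3,
                 k_m2 = k_m2, k3 = k3, kcat = kcat,
                 sum_k5_km5 = sum_k5_km5,
                 se = list(k2 = se_k2, K_S = se_K_S, sum_km2_k3 = se_sum,
                           k_m2 = se_km2, k3 = se_k3, kcat = se_kcat,
                           sum_k5_km5 = se_sum_k5_km5),
                 flags = flags),
            class = "micro_rates")
}

#' @export
print.micro_rates <- function(x, ...) {
  cat("Extracted microscopic rate constants\n")
  cat(sprintf("  k2  = %.4g +/- %.3g s^-1,  K_S = %.4g +/- %.3g uM\n",
              x$k2, x$se$k2, x$K_S, x$se$K_S))
  cat(sprintf("  k-2 = %.4g +/- %.3g s^-1,  k3  = %.4g +/- %.3g s^-1\n",
              x$k_m2, x$se$k_m2, x$k3, x$se$k3))
  cat(sprintf("  (k-2 + k3 = %.4g, kcat = %.4g s^-1)\n",
              x$sum_km2_k3, x$kcat))
  if (!is.null(x$sum_k5_km5))
    cat(sprintf("  k5 + k-5 = %.4g +/- %.3g s^-1\n",
                x$sum_k5_km5, x$se$sum_k5_km5))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.micro_rates <- function(object, ...) {
  c(k2 = object$k2, K_S = object$K_S, k_m2 = object$k_m2, k3 = object$k3)
}
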