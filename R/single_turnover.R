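#' Hydrolysis rate constant from a single-turnover trace
#'
#' Under single-turnover conditions ([E] and [S] both far above K_S,
#' enzyme in slight excess) essentially all substrate is bound at
#' mixing, every alkylenzyme formed proceeds once through hydrolysis,
#' and the fluorescence recovery after the initial quench relaxes at
#' the hydrolysis rate: k_obs of the recovery phase ~= k3. The recovery
#' window is taken from the signal minimum onward and fitted with a
#' single exponential with floating endpoint; a second pass restarts
#' the window one relaxation time later so that the faster
#' alkylation-phase component has decayed out of the fitted range.
#'
#' Note that the identification k_obs ~= k3 is itself an approximation:
#' when de-alkylation (k-2) is not negligible the recovery relaxes at
#' the slow eigenvalue of the saturated ES <-> E-alkyl -> E + P
#' subsystem, which lies below k3 by roughly the factor
#' k2/(k2 + k-2 + k3 - k_obs). The function returns the observed rate;
#' interpreting it as k3 is the caller's (standard) approximation.
#'
#' @param trace a [kin_trace()] recorded in single-turnover mode.
#' @param K_S optional dissociation constant (uM); when supplied, a
#'   warning is issued if min([E], [S]) < 2 K_S, below which the
#'   saturation assumption biases the recovered rate low.
#' @return list with `k3`, `se`, the underlying `fit` (an `exp_fit`)
#'   and `flags`.
#' @export
single_turnover_k3 <- function(trace, K_S = NULL) {
  stopifnot(inherits(trace, "kin_trace"))
  if (trace$conditions$mode != "single_turnover")
    stop("single_turnover_k3 requires a single-turnover trace",
         call. = FALSE)
  if (!is.null(K_S)) {
    sat <- min(trace$conditions$E_total, trace$conditions$S_total) / K_S
    if (sat < 2)
      warning(sprintf("saturation [min(E,S) = %.2g x K_S] below 2x; ",
                      sat),
              "recovered rate will underestimate k3")
  }
  keep <- trace$time >= trace$dead_time
  t <- trace$time[keep]; y <- trace$signal[keep]
  rng <- diff(range(y))
  if (rng < 1e-12 * max(abs(y), 1)) {
    return(list(k3 = NA_real_, se = NA_real_, fit = NULL,
                flags = "flat_trace_no_recovery"))
  }
  i_min <- which.min(y)
  if (length(y) - i_min + 1L < 20L) {
    # quench without recovery within the record (e.g. hydrolysis-dead)
    return(list(k3 = NA_real_, se = NA_real_, fit = NULL,
                flags = "flat_trace_no_recovery"))
  }
  sub <- kin_trace(t[i_min:length(t)], y[i_min:length(y)],
                   trace$conditions, n_averaged = trace$n_averaged,
                   dead_time = 0)
  fit <- fit_exponential(sub, 1L)
  # second pass: drop the first relaxation time of the recovery so the
  # residual fast (alkylation) component does not bias the rate low
  if (!"amplitude_near_zero" %in% fit$flags && is.finite(fit$k_obs[1]) &&
      fit$k_obs[1] > 0) {
    t_start <- t[i_min] + 1 / fit$k_obs[1]
    keep2 <- which(t >= t_start)
    if (length(keep2) >= 3L * 9L) {
      sub2 <- kin_trace(t[keep2], y[keep2], trace$conditions,
                        n_averaged = trace$n_averaged, dead_time = 0)
      fit2 <- tryCatch(fit_exponential(sub2, 1L), error = function(e) NULL)
      if (!is.null(fit2) && is.finite(fit2$k_obs[1])) fit <- fit2
    }
  }
  flags <- fit$flags
  # recovery amplitude negligible against the full quench depth
  if ("amplitude_near_zero" %in% flags ||
      max(abs(fit$amplitudes)) < 1e-3 * rng)
    flags <- union(flags, "flat_trace_no_recovery")
  list(k3 = fit$k_obs[1], se = fit$se$k_obs[1], fit = fit, flags = flags)
}
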