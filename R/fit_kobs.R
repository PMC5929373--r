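#' Observed-rate series over substrate concentration
#'
#' Collects transient rates `k_obs` determined at a series of substrate
#' concentrations, together with their standard errors and a phase
#' label (`"fast"` or `"slow"`), ready for regression against the
#' hyperbolic or decreasing concentration-dependence models.
#'
#' @param substrate_uM unique, positive substrate concentrations (uM).
#' @param kobs observed rates (s^-1).
#' @param se standard errors of `kobs` (optional, used as
#'   inverse-variance weights).
#' @param phase `"fast"` or `"slow"`.
#' @return an object of class `kobs_series`.
#' @export
kobs_series <- function(substrate_uM, kobs, se = NULL,
                        phase = c("fast", "slow")) {
  phase <- match.arg(phase)
  if (length(substrate_uM) != length(kobs))
    stop("substrate_uM and kobs must have equal length", call. = FALSE)
  if (any(substrate_uM <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (anyDuplicated(substrate_uM))
    stop("concentrations must be unique", call. = FALSE)
  if (!is.null(se) && length(se) != length(kobs))
    stop("se must match kobs in length", call. = FALSE)
  o <- order(substrate_uM)
  structure(list(substrate_uM = substrate_uM[o], kobs = kobs[o],
                 se = if (is.null(se)) NULL else se[o], phase = phase),
            class = "kobs_series")
}

#' @export
print.kobs_series <- function(x, ...) {
  cat(sprintf("k_obs series (%s phase): %d concentrations, %g-%g uM\n",
              x$phase, length(x$kobs), min(x$substrate_uM),
              max(x$substrate_uM)))
  invisible(x)
}

#' Read / write a k_obs series as CSV
#'
#' Columns: `substrate_uM`, `kobs_per_s`, `se_per_s`, `phase`.
#'
#' @param series a [kobs_series()].
#' @param path CSV file path.
#' @export
write_kobs_series <- function(series, path) {
  stopifnot(inherits(series, "kobs_series"))
  df <- data.frame(substrate_uM = fmt_full(series$substrate_uM),
                   kobs_per_s = fmt_full(series$kobs),
                   se_per_s = if (is.null(series$se)) ""
                              else fmt_full(series$se),
                   phase = series$phase)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kobs_series
#' @export
read_kobs_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("substrate_uM", "kobs_per_s", "phase")
  if (!all(need %in% names(df)))
    stop("k_obs CSV must have columns substrate_uM, kobs_per_s, phase",
         call. = FALSE)
  se <- if ("se_per_s" %in% names(df) && !all(is.na(df$se_per_s)))
    as.numeric(df$se_per_s) else NULL
  kobs_series(df$substrate_uM, df$kobs_per_s, se = se,
              phase = as.character(df$phase[1]))
}

.kobs_weights <- function(series) {
  if (is.null(series$se)) rep(1, length(series$kobs))
  else ifelse(series$se > 0, 1 / series$se^2, max(1 / series$se[series$se > 0]^2))
}

.trend_slope <- function(series) {
  stats::coef(stats::lm(series$kobs ~ series$substrate_uM))[2]
}

#' Hyperbolic substrate dependence of the observed transient rate
#'
#' Fits \eqn{k_{obs}(S) = \frac{k_2 S}{K_S + S} + (k_{-2} + k_3)}, the
#' rapid-equilibrium-binding model in which the transient rate rises
#' hyperbolically from the intercept \eqn{k_{-2} + k_3} at S = 0 to
#' \eqn{k_2 + k_{-2} + k_3} at saturation. Inverse-variance weights are
#' used when the series carries standard errors. When the fitted K_S
#' exceeds the covered concentration range, the extrapolated `k2` and
#' `K_S` carry large standard errors and the result is flagged.
#'
#' @param series a [kobs_series()] with at least 4 concentrations.
#' @return an object of class `kobs_fit` with elements `model`
#'   (`"hyperbolic"`), `k2`, `K_S`, `intercept` (k-2 + k3), `se`,
#'   `sse`, `df`, `fitted`, `residuals`, `flags`.
#' @export
fit_kobs_hyperbolic <- function(series) {
  stopifnot(inherits(series, "kobs_series"))
  S <- series$substrate_uM; y <- series$kobs
  if (length(unique(S)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  flags <- character(0)
  rng <- diff(range(y))
  if (rng < 1e-10 * max(abs(y))) {
    # flat series: k2 ~ 0, K_S undetermined
    return(structure(list(model = "hyperbolic", k2 = 0, K_S = NA_real_,
                          intercept = mean(y),
                          se = list(k2 = NA_real_, K_S = NA_real_,
                                    intercept = stats::sd(y) / sqrt(length(y))),
                          sse = sum((y - mean(y))^2), df = length(y) - 1L,
                          fitted = rep(mean(y), length(y)),
                          residuals = y - mean(y),
                          flags = c("flat_series", "K_S_undetermined"),
                          series = series),
                     class = "kobs_fit"))
  }
  slope <- .trend_slope(series)
  if (slope < 0 && stats::cor(S, y) < -0.5)
    stop("k_obs decreases with [S]; fit the decreasing (two-step) model ",
         "with fit_kobs_decreasing()", call. = FALSE)
  w <- .kobs_weights(series)
  start <- list(k2 = max(rng, 1e-6), K_S = stats::median(S),
                c0 = max(min(y), 1e-8))
  fit <- minpack.lm::nlsLM(y ~ k2 * S / (K_S + S) + c0,
                           start = start, weights = w,
                           lower = c(0, 1e-12, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, 3))
  if (is.finite(cf["K_S"]) && cf["K_S"] > max(S))
    flags <- c(flags, "extrapolated_K_S")
  if (!anyNA(ses) && (ses["k2"] > cf["k2"] || ses["K_S"] > cf["K_S"]))
    flags <- c(flags, "weakly_identified")
  res <- y - stats::fitted(fit)
  structure(list(model = "hyperbolic",
                 k2 = unname(cf["k2"]), K_S = unname(cf["K_S"]),
                 intercept = unname(cf["c0"]),
                 se = list(k2 = unname(ses["k2"]), K_S = unname(ses["K_S"]),
                           intercept = unname(ses["c0"])),
                 sse = sum(res^2), df = length(y) - 3L,
                 fitted = as.numeric(stats::fitted(fit)),
                 residuals = as.numeric(res), flags = flags,
                 series = series),
            class = "kobs_fit")
}

#' Decreasing substrate dependence of the observed transient rate
#'
#' Fits the two-step relaxation model for an observed rate that falls
#' with increasing substrate concentration,
#' \eqn{k_{obs}(S) = k_{lim} + \frac{k_{rev}}{1 + S/K_{app}}}: a
#' substrate-independent isomerization (either of the free enzyme,
#' k0 + k-0, or of the Michaelis complexes, k5 + k-5) observed through
#' progressively deeper saturation. The S -> 0 intercept
#' \eqn{k_{lim} + k_{rev}} estimates the summed forward and reverse
#' isomerization rates; which conformational step it reports is left to
#' the caller's labelling.
#'
#' @param series a [kobs_series()] with at least 4 concentrations and a
#'   decreasing trend.
#' @return an object of class `kobs_fit` with elements `model`
#'   (`"decreasing"`), `k_lim`, `k_rev`, `K_app`, `intercept`
#'   (`k_lim + k_rev`, the rate sum at S = 0), `se`, `sse`, `df`,
#'   `fitted`, `residuals`, `flags`.
#' @export
fit_kobs_decreasing <- function(series) {
  stopifnot(inherits(series, "kobs_series"))
  S <- series$substrate_uM; y <- series$kobs
  if (length(unique(S)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  rng <- diff(range(y))
  if (rng < 1e-10 * max(abs(y))) {
    # flat series: k_rev ~ 0, intercept = k_lim
    return(structure(list(model = "decreasing", k_lim = mean(y), k_rev = 0,
                          K_app = NA_real_, intercept = mean(y),
                          se = list(k_lim = stats::sd(y) / sqrt(length(y)),
                                    k_rev = NA_real_, K_app = NA_real_,
                                    intercept = stats::sd(y) / sqrt(length(y))),
                          sse = sum((y - mean(y))^2), df = length(y) - 1L,
                          fitted = rep(mean(y), length(y)),
                          residuals = y - mean(y),
                          flags = "flat_series", series = series),
                     class = "kobs_fit"))
  }
  if (.trend_slope(series) > 0)
    stop("k_obs increases with [S]; fit the hyperbolic model with ",
         "fit_kobs_hyperbolic()", call. = FALSE)
  w <- .kobs_weights(series)
  start <- list(k_lim = max(min(y), 1e-8), k_rev = max(rng, 1e-6),
                K_app = stats::median(S))
  fit <- minpack.lm::nlsLM(y ~ k_lim + k_rev / (1 + S / K_app),
                           start = start, weights = w,
                           lower = c(0, 0, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  ses <- if (is.null(V)) rep(NA_real_, 3) else sqrt(diag(V))
  names(ses) <- names(cf)
  # intercept = k_lim + k_rev, SE includes their covariance
  se_int <- if (is.null(V)) NA_real_ else
    sqrt(V["k_lim", "k_lim"] + V["k_rev", "k_rev"] +
           2 * V["k_lim", "k_rev"])
  res <- y - stats::fitted(fit)
  structure(list(model = "decreasing",
                 k_lim = unname(cf["k_lim"]), k_rev = unname(cf["k_rev"]),
                 K_app = unname(cf["K_app"]),
                 intercept = unname(cf["k_lim"] + cf["k_rev"]),
                 se = list(k_lim = unname(ses["k_lim"]),
                           k_rev = unname(ses["k_rev"]),
                           K_app = unname(ses["K_app"]),
                           intercept = se_int),
                 sse = sum(res^2), df = length(y) - 3L,
                 fitted = as.numeric(stats::fitted(fit)),
                 residuals = as.numeric(res), flags = character(0),
                 series = series),
            class = "kobs_fit")
}

#' @export
print.kobs_fit <- function(x, ...) {
  if (x$model == "hyperbolic") {
    cat(sprintf("Hyperbolic k_obs fit: k2 = %.4g +/- %.3g s^-1, K_S = %.4g +/- %.3g uM\n",
                x$k2, x$se$k2, x$K_S, x$se$K_S))
    cat(sprintf("  intercept (k-2 + k3) = %.4g +/- %.3g s^-1\n",
                x$intercept, x$se$intercept))
  } else {
    cat(sprintf("Decreasing k_obs fit: intercept (rate sum at S=0) = %.4g +/- %.3g s^-1\n",
                x$intercept, x$se$intercept))
    cat(sprintf("  k_lim = %.4g, k_rev = %.4g, K_app = %.4g uM\n",
                x$k_lim, x$k_rev, x$K_app))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.kobs_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$series$substrate_uM else {
    if (is.list(newdata)) newdata$substrate_uM else newdata
  }
  if (object$model == "hyperbolic")
    object$k2 * S / (object$K_S + S) + object$intercept
  else
    object$k_lim + object$k_rev / (1 + S / object$K_app)
}

#' @export
residuals.kobs_fit <- function(object, ...) object$residuals

#' @export
plot.kobs_fit <- function(x, ...) {
  S <- x$series$substrate_uM
  plot(S, x$series$kobs, pch = 16, xlab = "[S] (uM)",
       ylab = "k_obs (s^-1)", ...)
  Sg <- seq(min(S), max(S), length.out = 200)
  graphics::lines(Sg, predict(x, Sg), col = 2, lwd = 2)
  invisible(x)
}
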