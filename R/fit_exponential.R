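# Exponential fitting of stopped-flow traces.
#
# Model: F(t) = endpoint + sum_i A_i * exp(-k_obs_i * (t - t0)),
# where t0 is the first fitted time point (amplitudes are reported at
# the start of the observed window, which keeps the design matrix well
# conditioned for fast phases behind a dead time).
#
# Strategy: variable projection. For trial rates the amplitudes and the
# floating endpoint are linear parameters solved exactly by least
# squares, so the rate space is searched on a log-spaced multistart
# grid (4 points per decade over 1e-2..1e4 s^-1) and the best start is
# refined by minimizing the profiled SSE over log-rates. Deterministic
# given the data.

.RATE_GRID <- 10^seq(-2, 4, by = 0.25)

.vp_sse <- function(logk, t, y) {
  k <- exp(logk)
  X <- cbind(1, exp(-outer(t, k)))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

.vp_solve <- function(k, t, y) {
  X <- cbind(1, exp(-outer(t, k)))
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0   # rank deficiency: collapsed duplicate phases
  list(endpoint = cf[1],
       amplitudes = cf[-1],
       fitted = X %*% cf,
       sse = sum((y - X %*% cf)^2))
}

#' Fit a single or double exponential with floating endpoint
#'
#' Least-squares fit of
#' \eqn{F(t) = F_\infty + \sum_{i=1}^{m} A_i e^{-k_{obs,i} t}} (m = 1 or
#' 2) to a stopped-flow trace, the standard models for pre-steady-state
#' alkylenzyme buildup and decay. Points before the trace's dead time
#' are excluded. Parameter standard errors come from the regression
#' covariance (Gauss approximation at the optimum).
#'
#' @param trace a [kin_trace()].
#' @param order number of exponential phases, 1 or 2.
#' @return an object of class `exp_fit` with elements `order`, `k_obs`
#'   (s^-1, sorted decreasing), `amplitudes` (signal units, aligned with
#'   `k_obs`, referenced to the first fitted time point `t0`),
#'   `endpoint`, `sse`, `df`, `se` (list of standard errors), `fitted`,
#'   `residuals`, `flags`.
#' @examples
#' cond <- reaction_conditions(1, 500)
#' t <- seq(0, 0.1, length.out = 100)
#' tr <- kin_trace(t, 0.2 + exp(-100 * t), cond)
#' fit_exponential(tr, 1)
#' @export
fit_exponential <- function(trace, order = 1L) {
  stopifnot(inherits(trace, "kin_trace"))
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  order <- as.integer(order)
  keep <- trace$time >= trace$dead_time
  t_raw <- trace$time[keep]
  y <- trace$signal[keep]
  n <- length(y)
  npar <- 2L * order + 1L
  if (n < 3L * npar)
    stop(sprintf("trace has %d usable points; need at least %d for an order-%d fit",
                 n, 3L * npar, order), call. = FALSE)
  t0 <- t_raw[1]
  t <- t_raw - t0

  # multistart over the rate grid
  if (order == 1L) {
    sses <- vapply(.RATE_GRID, function(k) .vp_sse(log(k), t, y), 0)
    if (all(!is.finite(sses)))
      stop("exponential fit failed: no finite SSE on the start grid",
           call. = FALSE)
    k_start <- .RATE_GRID[which.min(sses)]
    opt <- stats::optim(log(k_start), .vp_sse, t = t, y = y,
                        method = "Brent",
                        lower = log(k_start) - 3, upper = log(k_start) + 3)
    k_hat <- exp(opt$par)
  } else {
    idx <- utils::combn(seq_along(.RATE_GRID), 2)
    sses <- apply(idx, 2, function(ij)
      .vp_sse(log(.RATE_GRID[ij]), t, y))
    if (all(!is.finite(sses)))
      stop("exponential fit failed: no finite SSE on the start grid",
           call. = FALSE)
    best <- idx[, which.min(sses)]
    opt <- stats::optim(log(.RATE_GRID[best]), .vp_sse, t = t, y = y,
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    k_hat <- exp(opt$par)
  }

  ord <- order(k_hat, decreasing = TRUE)
  k_hat <- k_hat[ord]
  sol <- .vp_solve(k_hat, t, y)
  A <- as.numeric(sol$amplitudes)
  b0 <- as.numeric(sol$endpoint)
  sse <- sol$sse
  df <- n - npar

  # Gauss-approximation covariance at the optimum
  Ecols <- exp(-outer(t, k_hat))
  J <- cbind(1, Ecols, -t * Ecols * rep(A, each = n))
  sigma2 <- sse / df
  cov <- tryCatch(sigma2 * solve(crossprod(J)),
                  error = function(e) NULL)
  flags <- character(0)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    se_b0 <- NA_real_; se_A <- rep(NA_real_, order)
    se_k <- rep(NA_real_, order)
    flags <- c(flags, "ill_determined")
  } else {
    ses <- sqrt(diag(cov))
    se_b0 <- ses[1]; se_A <- ses[2:(1 + order)]
    se_k <- ses[(2 + order):npar]
  }
  amp_scale <- max(abs(diff(range(y))), 1e-8 * max(abs(y), 1))
  if (any(abs(A) <= 1e-3 * amp_scale) ||
      (!anyNA(se_A) && any(abs(A) < 2 * se_A)))
    flags <- c(flags, "amplitude_near_zero")
  if (!anyNA(se_k) && any(se_k > abs(k_hat)))
    flags <- c(flags, "rate_ill_determined")
  if (order == 2L && k_hat[1] < 1.05 * k_hat[2])
    flags <- c(flags, "degenerate_phases")

  structure(list(order = order, k_obs = k_hat, amplitudes = A,
                 endpoint = b0, sse = sse, df = df, n = n, t0 = t0,
                 se = list(k_obs = se_k, amplitudes = se_A,
                           endpoint = se_b0),
                 fitted = as.numeric(sol$fitted),
                 residuals = y - as.numeric(sol$fitted),
                 time = t_raw, signal = y, flags = flags),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit (order %d, %d points, SSE %.4g)\n",
              x$order, x$n, x$sse))
  for (i in seq_len(x$order))
    cat(sprintf("  k_obs%d = %.5g +/- %.3g s^-1, amplitude %.4g +/- %.3g\n",
                i, x$k_obs[i], x$se$k_obs[i], x$amplitudes[i],
                x$se$amplitudes[i]))
  cat(sprintf("  endpoint = %.5g +/- %.3g\n", x$endpoint, x$se$endpoint))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  k <- object$k_obs; A <- object$amplitudes
  stats::setNames(c(object$endpoint, A, k),
                  c("endpoint",
                    paste0("A", seq_along(A)),
                    paste0("k_obs", seq_along(k))))
}

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else {
    if (is.list(newdata)) newdata$time else newdata
  }
  tt <- t - object$t0
  object$endpoint +
    rowSums(exp(-outer(tt, object$k_obs)) *
              rep(object$amplitudes, each = length(tt)))
}

#' @export
fitted.exp_fit <- function(object, ...) object$fitted

#' @export
residuals.exp_fit <- function(object, ...) object$residuals

#' @export
plot.exp_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$time, x$signal, pch = 16, cex = 0.4, xlab = "time (s)",
       ylab = "fluorescence (a.u.)", ...)
  graphics::lines(x$time, x$fitted, col = 2, lwd = 2)
  plot(x$time, x$residuals, pch = 16, cex = 0.4, xlab = "time (s)",
       ylab = "residual")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Select exponential fit order by extra-sum-of-squares F-test
#'
#' Compares a nested pair of exponential fits on the same trace:
#' \eqn{F = \frac{(SSE_1 - SSE_2)/(df_1 - df_2)}{SSE_2/df_2}}. The
#' higher order is retained only when it improves the fit significantly
#' at level `alpha`.
#'
#' @param fit1 the lower-order `exp_fit`.
#' @param fit2 the higher-order `exp_fit` (same trace).
#' @param alpha significance level, default 0.05.
#' @return list with `order` (the chosen order), `F`, `p_value`,
#'   `alpha`.
#' @export
select_order <- function(fit1, fit2, alpha = 0.05) {
  stopifnot(inherits(fit1, "exp_fit"), inherits(fit2, "exp_fit"))
  if (fit1$order >= fit2$order)
    stop("fit2 must have higher order than fit1", call. = FALSE)
  if (fit1$n != fit2$n)
    stop("fits must be on the same trace", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (fit2$sse > fit1$sse) {
    warning("higher-order fit has larger SSE; keeping order ", fit1$order)
    return(list(order = fit1$order, F = 0, p_value = 1, alpha = alpha))
  }
  ddf <- fit1$df - fit2$df
  Fstat <- ((fit1$sse - fit2$sse) / ddf) / (fit2$sse / fit2$df)
  p <- stats::pf(Fstat, ddf, fit2$df, lower.tail = FALSE)
  list(order = if (p < alpha) fit2$order else fit1$order,
       F = Fstat, p_value = p, alpha = alpha)
}
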