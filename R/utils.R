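# Internal helpers shared across the package.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L)
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Format numbers for text files so that read-back is lossless in double
# precision.
fmt_full <- function(x) sprintf("%.17g", x)

#' Wald-Wolfowitz runs test on residual signs
#'
#' Diagnostic for systematic misfit: residuals from a correctly specified
#' least-squares model should change sign often; a lag of consecutive
#' same-sign residuals indicates a missing phase. Normal approximation to
#' the null distribution of the number of sign runs.
#'
#' @param residuals numeric vector of residuals (zeros are dropped).
#' @return list with `n_runs`, `expected`, `z` and two-sided `p_value`.
#' @export
runs_test <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n <- length(s)
  if (n < 10L) stop("need at least 10 nonzero residuals", call. = FALSE)
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  runs <- 1L + sum(s[-1] != s[-n])
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(list(n_runs = runs, expected = mu, z = NA_real_,
                          p_value = NA_real_))
  z <- (runs - mu) / sqrt(v)
  list(n_runs = runs, expected = mu, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}
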