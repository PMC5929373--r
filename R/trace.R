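#' Stopped-flow fluorescence trace
#'
#' A (possibly replicate-averaged) fluorescence time series together
#' with the experimental conditions under which it was recorded.
#' Points before `dead_time` (instrument mixing dead time) are kept in
#' the object but excluded from fitting.
#'
#' @param time strictly increasing sampling times (s), at least 20.
#' @param signal fluorescence (arbitrary units), same length as `time`.
#' @param conditions a [reaction_conditions()].
#' @param n_averaged number of replicate traces averaged (>= 1;
#'   experimental practice averages at least six).
#' @param dead_time instrument dead time (s); default 0.
#' @return an object of class `kin_trace`.
#' @export
kin_trace <- function(time, signal, conditions, n_averaged = 1L,
                      dead_time = 0) {
  stopifnot(inherits(conditions, "reaction_conditions"))
  if (!is.numeric(time) || !is.numeric(signal) ||
      length(time) != length(signal))
    stop("time and signal must be numeric vectors of equal length",
         call. = FALSE)
  if (length(time) < 20L)
    stop("a trace needs at least 20 samples", call. = FALSE)
  if (any(!is.finite(time)) || any(!is.finite(signal)))
    stop("time and signal must be finite", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  check_scalar(n_averaged, "n_averaged")
  if (n_averaged < 1) stop("n_averaged must be >= 1", call. = FALSE)
  check_scalar(dead_time, "dead_time", nonneg = TRUE)
  structure(list(time = time, signal = signal, conditions = conditions,
                 n_averaged = as.integer(n_averaged),
                 dead_time = dead_time),
            class = "kin_trace")
}

#' @export
print.kin_trace <- function(x, ...) {
  cat(sprintf("Stopped-flow trace: %d samples over %g s (avg of %d), %s\n",
              length(x$time), max(x$time), x$n_averaged,
              x$conditions$mode))
  invisible(x)
}

#' @export
plot.kin_trace <- function(x, ...) {
  plot(x$time, x$signal, type = "l", xlab = "time (s)",
       ylab = "fluorescence (a.u.)", ...)
  if (x$dead_time > 0) graphics::abline(v = x$dead_time, lty = 3)
  invisible(x)
}

#' Read / write a trace as CSV plus a YAML metadata sidecar
#'
#' The CSV carries columns `time_s` and `signal` at full double
#' precision; the sidecar (same path with extension `.yaml`) carries
#' `enzyme_uM`, `substrate_uM`, `temperature_K`, `mode`, `n_averaged`
#' and `dead_time_s`.
#'
#' @param trace a [kin_trace()].
#' @param path CSV file path.
#' @return `read_trace` returns a [kin_trace()]; `write_trace` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kin_trace"))
  df <- data.frame(time_s = fmt_full(trace$time),
                   signal = fmt_full(trace$signal))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(enzyme_uM = trace$conditions$E_total,
               substrate_uM = trace$conditions$S_total,
               temperature_K = trace$conditions$temperature,
               mode = trace$conditions$mode,
               n_averaged = trace$n_averaged,
               dead_time_s = trace$dead_time)
  yaml::write_yaml(meta, .sidecar_path(path), precision = 15L)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "signal") %in% names(df)))
    stop("trace CSV must have columns time_s, signal", call. = FALSE)
  meta <- yaml::read_yaml(sidecar)
  cond <- reaction_conditions(E_total = meta$enzyme_uM,
                              S_total = meta$substrate_uM,
                              temperature = meta$temperature_K,
                              mode = meta$mode)
  kin_trace(df$time_s, df$signal, cond,
            n_averaged = meta$n_averaged, dead_time = meta$dead_time_s)
}

.sidecar_path <- function(path) sub("\\.[^.]+$", ".yaml", path)
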