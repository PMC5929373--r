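#' Experimental reaction conditions
#'
#' Enzyme and substrate concentrations, temperature and turnover mode of
#' a stopped-flow experiment. Multiple-turnover (pseudo-first-order)
#' conditions require the enzyme concentration to be at least tenfold
#' below the substrate concentration; single-turnover experiments use
#' near-stoichiometric enzyme excess at saturating concentrations.
#'
#' @param E_total total enzyme concentration (uM).
#' @param S_total total substrate concentration (uM).
#' @param temperature temperature (K), default 303.15 (30 C assay
#'   temperature).
#' @param mode `"multiple_turnover"` or `"single_turnover"`.
#' @return an object of class `reaction_conditions`.
#' @examples
#' reaction_conditions(E_total = 1, S_total = 500)
#' @export
reaction_conditions <- function(E_total, S_total,
                                temperature = 303.15,
                                mode = c("multiple_turnover",
                                         "single_turnover")) {
  mode <- match.arg(mode)
  check_scalar(E_total, "E_total", positive = TRUE)
  check_scalar(S_total, "S_total", positive = TRUE)
  check_scalar(temperature, "temperature", positive = TRUE)
  if (temperature < 273 || temperature > 373)
    stop("temperature must be within 273-373 K", call. = FALSE)
  if (mode == "multiple_turnover" && E_total > S_total / 10)
    stop("multiple-turnover conditions require E_total <= S_total/10 ",
         "(pseudo-first-order criterion)", call. = FALSE)
  structure(list(E_total = E_total, S_total = S_total,
                 temperature = temperature, mode = mode),
            class = "reaction_conditions")
}

#' @export
print.reaction_conditions <- function(x, ...) {
  cat(sprintf("Reaction conditions: E = %g uM, S = %g uM, T = %g K, %s\n",
              x$E_total, x$S_total, x$temperature, x$mode))
  invisible(x)
}

#' @rdname reaction_conditions
#' @param path file path for YAML serialization.
#' @export
read_conditions <- function(path) {
  y <- yaml::read_yaml(path)
  reaction_conditions(E_total = y$E_total, S_total = y$S_total,
                      temperature = y$temperature, mode = y$mode)
}

#' @rdname reaction_conditions
#' @param cond a `reaction_conditions` object.
#' @export
write_conditions <- function(cond, path) {
  stopifnot(inherits(cond, "reaction_conditions"))
  yaml::write_yaml(unclass(cond), path, precision = 15L)
  invisible(path)
}
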