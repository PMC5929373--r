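#' Microscopic rate constants of the branched alkylenzyme scheme
#'
#' Container for the full set of microscopic rate constants of the
#' two-branch epoxide-hydrolase mechanism: a free-enzyme conformational
#' step E <-> E', substrate binding to either conformer (dissociation
#' constants K_S and K_S'), interconversion of the two Michaelis
#' complexes ES <-> E'S (k5, k-5), reversible alkylation on each branch
#' (k2, k-2 and k2', k-2'), and hydrolysis of each alkylenzyme lumped
#' with product release (k3, k3'). Binding is realized explicitly with a
#' bimolecular association rate `kon` and `koff = kon * K_S`, so the
#' rapid-equilibrium treatment usual in transient kinetics is an emergent
#' limit rather than a built-in assumption.
#'
#' Setting `k2_prime = k3_prime = k5 = k_m5 = k0 = k_m0 = 0` reduces the
#' scheme to the linear three-step mechanism E + S <-> ES <-> E-alkyl ->
#' E + P.
#'
#' @param k2,k_m2 alkylation / de-alkylation rate constants on the
#'   primary branch (s^-1).
#' @param k3 hydrolysis rate constant of the primary alkylenzyme,
#'   including product release (s^-1).
#' @param K_S substrate dissociation constant of ES (uM).
#' @param k2_prime,k_m2_prime,k3_prime same for the alternative branch
#'   (s^-1).
#' @param K_S_prime dissociation constant of E'S (uM); defaults to `K_S`.
#' @param k5,k_m5 ES <-> E'S interconversion rate constants (s^-1).
#' @param k0,k_m0 E <-> E' free-enzyme conformational rate constants
#'   (s^-1); default 0 (single free conformer).
#' @param kon bimolecular association rate constant (uM^-1 s^-1),
#'   default 1000, near the diffusion limit.
#' @return an object of class `rate_set`.
#' @examples
#' rs <- rate_set(k2 = 370, k_m2 = 170, k3 = 110, K_S = 470,
#'                k5 = 16, k_m5 = 16)
#' rs
#' @export
rate_set <- function(k2, k_m2, k3, K_S,
                     k2_prime = 0, k_m2_prime = 0, k3_prime = 0,
                     K_S_prime = K_S,
                     k5 = 0, k_m5 = 0, k0 = 0, k_m0 = 0,
                     kon = 1000) {
  vals <- list(k0 = k0, k_m0 = k_m0, K_S = K_S, K_S_prime = K_S_prime,
               k2 = k2, k_m2 = k_m2, k2_prime = k2_prime,
               k_m2_prime = k_m2_prime, k3 = k3, k3_prime = k3_prime,
               k5 = k5, k_m5 = k_m5, kon = kon)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("rate_set field '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  for (nm in c("k0", "k_m0", "k2", "k_m2", "k2_prime", "k_m2_prime",
               "k3", "k3_prime", "k5", "k_m5"))
    if (vals[[nm]] < 0)
      stop(sprintf("rate_set field '%s' must be >= 0", nm), call. = FALSE)
  for (nm in c("K_S", "K_S_prime", "kon"))
    if (vals[[nm]] <= 0)
      stop(sprintf("rate_set field '%s' must be > 0", nm), call. = FALSE)
  if (!is.finite(vals$kon * vals$K_S) || !is.finite(vals$kon * vals$K_S_prime))
    stop("implied koff = kon * K_S overflows", call. = FALSE)
  structure(vals, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Branched-scheme rate set\n")
  cat(sprintf("  binding:     kon = %g uM^-1 s^-1, K_S = %g uM, K_S' = %g uM\n",
              x$kon, x$K_S, x$K_S_prime))
  cat(sprintf("  alkylation:  k2 = %g, k-2 = %g | k2' = %g, k-2' = %g s^-1\n",
              x$k2, x$k_m2, x$k2_prime, x$k_m2_prime))
  cat(sprintf("  hydrolysis:  k3 = %g | k3' = %g s^-1\n", x$k3, x$k3_prime))
  cat(sprintf("  conformers:  k0 = %g, k-0 = %g; k5 = %g, k-5 = %g s^-1\n",
              x$k0, x$k_m0, x$k5, x$k_m5))
  invisible(x)
}

#' Test whether a rate set is effectively the linear three-step scheme
#' @param rates a [rate_set()].
#' @return logical.
#' @export
is_linear_scheme <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  all(c(rates$k2_prime, rates$k3_prime, rates$k5, rates$k_m5,
        rates$k0, rates$k_m0) == 0)
}

#' Read / write a rate set as YAML
#'
#' Keys are exactly the field names of [rate_set()]; units are fixed
#' (s^-1, uM, uM^-1 s^-1) and never embedded in the values.
#'
#' @param path file path.
#' @param rates a [rate_set()].
#' @return `read_rate_set` returns a [rate_set()]; `write_rate_set`
#'   returns `path` invisibly.
#' @export
read_rate_set <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(rate_set, y)
}

#' @rdname read_rate_set
#' @export
write_rate_set <- function(rates, path) {
  stopifnot(inherits(rates, "rate_set"))
  yaml::write_yaml(unclass(rates), path, precision = 15L)
  invisible(path)
}
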