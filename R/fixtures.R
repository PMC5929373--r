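# Published kinetic-parameter fixtures for the StEH1 variant panel.
# One YAML file per variant x substrate row under
# inst/extdata/table1/; only values actually reported are present,
# missing cells stay unset.

.fixture_token <- function(x) gsub("[^A-Za-z0-9]+", "", x)

.fixture_variants <- c("wild_type", "R-C1", "R-C1B1", "R-C1B1D33",
                       "R-C1B1D33E6")
.fixture_substrates <- c("(R,R)-1a", "(S,S)-1a", "(R,R)-1b", "(S,S)-1b")

#' Published kinetic parameters for an StEH1 variant / substrate pair
#'
#' Loads the fixture encoding the published steady-state and
#' pre-steady-state parameters (kcat, Km, kcat/Km, K_S, k2, k-2, k3,
#' k5 + k-5, each with its standard error where reported) for one
#' enzyme variant and one substrate enantiomer. Values never reported
#' for that pair are absent from the fixture; requesting a pair for
#' which no numeric parameter exists (only a bound or a dash was
#' published) is an error.
#'
#' @param variant one of `"wild_type"`, `"R-C1"`, `"R-C1B1"`,
#'   `"R-C1B1D33"`, `"R-C1B1D33E6"`.
#' @param substrate one of `"(R,R)-1a"`, `"(S,S)-1a"`, `"(R,R)-1b"`,
#'   `"(S,S)-1b"` (punctuation-insensitive, e.g. `"SS-1a"`).
#' @return an object of class `fixture_set`: `variant`, `substrate`,
#'   `values` (named list of reported numbers), `regioselectivity`,
#'   `notes`, `provenance`.
#' @examples
#' fx <- table1_fixture("wild_type", "(S,S)-1a")
#' fx$values$k2
#' @export
table1_fixture <- function(variant, substrate) {
  vtok <- .fixture_token(variant)
  stok <- .fixture_token(substrate)
  vmatch <- .fixture_variants[.fixture_token(.fixture_variants) == vtok]
  smatch <- .fixture_substrates[.fixture_token(.fixture_substrates) == stok]
  if (!length(vmatch))
    stop("unknown variant '", variant, "'; expected one of: ",
         paste(.fixture_variants, collapse = ", "), call. = FALSE)
  if (!length(smatch))
    stop("unknown substrate '", substrate, "'; expected one of: ",
         paste(.fixture_substrates, collapse = ", "), call. = FALSE)
  path <- system.file("extdata", "table1",
                      paste0(.fixture_token(vmatch), "_",
                             .fixture_token(smatch), ".yaml"),
                      package = "stehkin", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  if (length(y$values) == 0L)
    stop("kinetic parameters for ", vmatch, " with ", smatch,
         " are not reported",
         if (!is.null(y$notes)) paste0(" (", y$notes, ")"), call. = FALSE)
  structure(list(variant = y$variant, substrate = y$substrate,
                 values = y$values, regioselectivity = y$regioselectivity,
                 notes = y$notes, provenance = y$provenance),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("Fixture: %s / %s\n", x$variant, x$substrate))
  vals <- x$values[!grepl("_se$", names(x$values))]
  for (nm in names(vals)) {
    se_nm <- paste0(nm, "_se")
    if (se_nm %in% names(x$values))
      cat(sprintf("  %s = %g +/- %g\n", nm, x$values[[nm]],
                  x$values[[se_nm]]))
    else cat(sprintf("  %s = %g\n", nm, x$values[[nm]]))
  }
  if (!is.null(x$regioselectivity))
    cat("  regioselectivity:", x$regioselectivity, "\n")
  if (!is.null(x$notes)) cat("  notes:", x$notes, "\n")
  invisible(x)
}

#' Build a simulatable rate set from a fixture
#'
#' Requires the fixture to report the complete transient-parameter set
#' (k2, k-2, k3, K_S). The reported isomerization rate sum k5 + k-5,
#' when present, is split between forward and reverse rates by
#' `k5_split` (default 50/50, a documented convention: only the sum is
#' experimentally determined). The chemistry of the alternative branch
#' is left at zero, so the resulting scheme reduces to the linear
#' mechanism plus, when k5 + k-5 is reported, a reversible excursion of
#' the Michaelis complex to a non-productive conformer.
#'
#' @param fixture a [table1_fixture()] result.
#' @param k5_split fraction of the k5 + k-5 sum assigned to k5.
#' @param kon association rate constant (uM^-1 s^-1).
#' @param include_k5 logical; set `FALSE` to drop the isomerization
#'   step even when the sum is reported.
#' @return a [rate_set()].
#' @export
as_rate_set <- function(fixture, k5_split = 0.5, kon = 1000,
                        include_k5 = TRUE) {
  stopifnot(inherits(fixture, "fixture_set"))
  v <- fixture$values
  need <- c("k2", "k_m2", "k3", "K_S")
  missing <- setdiff(need, names(v))
  if (length(missing))
    stop("fixture ", fixture$variant, " / ", fixture$substrate,
         " lacks reported ", paste(missing, collapse = ", "),
         call. = FALSE)
  sum5 <- if (include_k5 && "sum_k5_km5" %in% names(v)) v$sum_k5_km5 else 0
  rate_set(k2 = v$k2, k_m2 = v$k_m2, k3 = v$k3, K_S = v$K_S,
           k5 = k5_split * sum5, k_m5 = (1 - k5_split) * sum5,
           kon = kon)
}

#' List the fixture rows with a complete transient rate set
#'
#' @return data frame of variant / substrate pairs for which k2, k-2,
#'   k3 and K_S are all reported.
#' @export
complete_fixtures <- function() {
  rows <- expand.grid(variant = .fixture_variants,
                      substrate = .fixture_substrates,
                      stringsAsFactors = FALSE)
  ok <- vapply(seq_len(nrow(rows)), function(i) {
    fx <- tryCatch(table1_fixture(rows$variant[i], rows$substrate[i]),
                   error = function(e) NULL)
    !is.null(fx) &&
      all(c("k2", "k_m2", "k3", "K_S") %in% names(fx$values))
  }, TRUE)
  rows[ok, , drop = FALSE]
}
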