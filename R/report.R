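# Report generation: JSON fit reports and the end-to-end run report
# (rates with standard errors, the derived activation-free-energy
# table, flux prediction and ee, stamped with version, input hashes and
# seeds).

#' Write a fit report as JSON
#'
#' Serializes an `exp_fit`, `kobs_fit`, `micro_rates` or `mm_fit`
#' together with optional F-test record and provenance (input file
#' hashes via MD5, seed) at full numeric precision.
#'
#' @param fit a fit object.
#' @param path output JSON path.
#' @param f_test optional result of [select_order()].
#' @param inputs optional character vector of input file paths to hash.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, f_test = NULL, inputs = NULL,
                             seed = NULL) {
  payload <- list(
    class = class(fit)[1],
    parameters = unclass(fit)[!names(unclass(fit)) %in%
                                c("fitted", "residuals", "time", "signal",
                                  "series", "fit")],
    f_test = f_test,
    provenance = list(
      package_version = as.character(utils::packageVersion("stehkin")),
      input_md5 = if (is.null(inputs)) NULL else
        as.list(tools::md5sum(inputs)),
      seed = seed))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' End-to-end analysis report for a variant / substrate pair
#'
#' Assembles the package's summary of one enzyme-substrate system: the
#' microscopic rates with standard errors, the activation free energies
#' derived from them by the Eyring relation (alkylation from k2,
#' hydrolysis from k3, overall turnover from kcat, at the configured
#' temperature, reported to 0.1 kcal/mol precision), and, when branch
#' barriers are supplied, the predicted flux partition and enantiomeric
#' excess.
#'
#' @param rates named list or `fixture_set` values carrying any of
#'   `k2`, `k_m2`, `k3`, `K_S`, `kcat`, `Km` and their `*_se`
#'   companions; a [table1_fixture()] object is accepted directly.
#' @param barriers optional [branch_barriers()] for the flux section.
#' @param temperature temperature (K) for the Eyring conversion.
#' @param seed seed recorded in (and used for) the flux-interval
#'   resampling.
#' @param inputs optional input file paths to hash into the report.
#' @return object of class `run_report`.
#' @export
run_report <- function(rates, barriers = NULL, temperature = 303.15,
                       seed = NULL, inputs = NULL) {
  vals <- if (inherits(rates, "fixture_set")) rates$values else rates
  label <- if (inherits(rates, "fixture_set"))
    paste(rates$variant, rates$substrate, sep = " / ") else "custom"
  if (!length(vals)) stop("no kinetic parameters supplied", call. = FALSE)

  dG <- list()
  for (entry in list(c("k2", "alkylation"), c("k3", "hydrolysis"),
                     c("kcat", "turnover"))) {
    nm <- entry[1]
    if (!is.null(vals[[nm]]) && vals[[nm]] > 0) {
      g <- eyring_barrier(vals[[nm]], temperature)
      se_nm <- paste0(nm, "_se")
      g_se <- if (!is.null(vals[[se_nm]]))
        .R_KCAL * temperature * vals[[se_nm]] / vals[[nm]] else NA_real_
      dG[[entry[2]]] <- list(from = nm, rate = vals[[nm]],
                            dG = round(g, 1), dG_se = g_se)
    }
  }
  if (!length(dG))
    warning("no positive rate among k2, k3, kcat: barrier table empty")

  flux <- NULL
  if (!is.null(barriers)) {
    pred <- branch_fractions_from_barriers(barriers, seed = seed)
    flux <- list(fractions = as.list(pred$fractions),
                 regioselectivity = pred$regioselectivity,
                 ee = pred$ee, dominant = pred$dominant,
                 interval = pred$interval)
  }
  structure(list(
    system = label, temperature_K = temperature,
    rates = vals, barriers_dG = dG, flux = flux,
    provenance = list(
      package_version = as.character(utils::packageVersion("stehkin")),
      input_md5 = if (is.null(inputs)) NULL else
        as.list(tools::md5sum(inputs)),
      seed = seed)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Analysis report:", x$system, "\n")
  cat(sprintf("  temperature: %g K\n", x$temperature_K))
  base <- x$rates[!grepl("_se$", names(x$rates))]
  for (nm in names(base)) {
    se <- x$rates[[paste0(nm, "_se")]]
    unit <- if (nm %in% c("K_S", "Km")) "uM"
            else if (nm == "kcat_over_Km") "s^-1 mM^-1" else "s^-1"
    if (!is.null(se))
      cat(sprintf("  %-12s %g +/- %g %s\n", nm, base[[nm]], se, unit))
    else cat(sprintf("  %-12s %g %s\n", nm, base[[nm]], unit))
  }
  if (length(x$barriers_dG)) {
    cat("  activation free energies (kcal/mol):\n")
    for (nm in names(x$barriers_dG)) {
      b <- x$barriers_dG[[nm]]
      cat(sprintf("    %-10s dG = %.1f (from %s = %g s^-1)\n",
                  nm, b$dG, b$from, b$rate))
    }
  }
  if (!is.null(x$flux))
    cat(sprintf("  flux: %s dominant, regioselectivity %.1f%%, ee %.1f%%\n",
                x$flux$dominant, x$flux$regioselectivity, x$flux$ee))
  invisible(x)
}

#' @rdname run_report
#' @param report a `run_report`.
#' @param path output JSON path.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
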