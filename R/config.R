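#' Validation configuration
#'
#' Bundles the acceptance thresholds and coverage settings used throughout a
#' validation run. Defaults follow common bioanalytical practice (ICH M10 /
#' EMA-style limits; accuracy-profile acceptance of +/-30 % with beta = 0.80,
#' measurement uncertainty at beta = 0.95).
#'
#' @param beta_profile coverage probability of the beta-expectation tolerance
#'   intervals drawn on accuracy profiles (default 0.80).
#' @param beta_mu coverage probability used for expanded measurement
#'   uncertainty (default 0.95).
#' @param acceptance_profile_pct accuracy-profile acceptance limit lambda, in
#'   percent of nominal (default 30).
#' @param qc_limit_pct limit applied to trueness/precision of routine QCs and
#'   to matrix-effect, stability, dilution and inter-laboratory deviations
#'   (default 15).
#' @param lloq_dev_pct accuracy limit at the LLOQ (default 20).
#' @param crosstalk_analyte_max_pct maximal tolerated interference of the
#'   internal standard in analyte detection, percent of CAL1 (default 20).
#' @param crosstalk_is_max_pct maximal tolerated interference of the analyte
#'   in internal-standard detection (default 5).
#' @param carryover_max_pct carryover limit relative to CAL1 (default 20).
#' @param sn_min minimal signal-to-noise ratio for detectability (default 3).
#' @param dilution_factor default dilution factor for dilution-integrity
#'   samples (default 10).
#' @param seed integer seed used by stochastic procedures, or `NULL`.
#'
#' @return an object of class `validation_config` (a named list).
#' @examples
#' cfg <- validation_config()
#' cfg$acceptance_profile_pct
#' @export
validation_config <- function(beta_profile = 0.80,
                              beta_mu = 0.95,
                              acceptance_profile_pct = 30,
                              qc_limit_pct = 15,
                              lloq_dev_pct = 20,
                              crosstalk_analyte_max_pct = 20,
                              crosstalk_is_max_pct = 5,
                              carryover_max_pct = 20,
                              sn_min = 3,
                              dilution_factor = 10,
                              seed = NULL) {
  stopifnot(
    is.numeric(beta_profile), length(beta_profile) == 1L,
    beta_profile > 0, beta_profile < 1,
    is.numeric(beta_mu), length(beta_mu) == 1L, beta_mu > 0, beta_mu < 1
  )
  limits <- c(acceptance_profile_pct, qc_limit_pct, lloq_dev_pct,
              crosstalk_analyte_max_pct, crosstalk_is_max_pct,
              carryover_max_pct, sn_min, dilution_factor)
  if (!all(is.finite(limits)) || any(limits <= 0)) {
    stop("all acceptance limits must be positive and finite", call. = FALSE)
  }
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(length(seed) == 1L, !is.na(seed))
  }
  structure(
    list(beta_profile = beta_profile, beta_mu = beta_mu,
         acceptance_profile_pct = acceptance_profile_pct,
         qc_limit_pct = qc_limit_pct, lloq_dev_pct = lloq_dev_pct,
         crosstalk_analyte_max_pct = crosstalk_analyte_max_pct,
         crosstalk_is_max_pct = crosstalk_is_max_pct,
         carryover_max_pct = carryover_max_pct, sn_min = sn_min,
         dilution_factor = dilution_factor, seed = seed),
    class = "validation_config"
  )
}

#' Read a validation configuration from a YAML file
#'
#' Every key is optional; omitted keys fall back to the defaults of
#' [validation_config()]. Unknown keys raise an error so typos do not pass
#' silently.
#'
#' @param path path to a YAML (or plain `key: value`) file.
#' @return a `validation_config`.
#' @export
read_validation_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(validation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(validation_config, raw)
}

#' @export
print.validation_config <- function(x, ...) {
  cat("Validation configuration\n")
  cat(sprintf("  accuracy profile: beta = %.2f, limits +/-%g%%\n",
              x$beta_profile, x$acceptance_profile_pct))
  cat(sprintf("  measurement uncertainty: beta = %.2f\n", x$beta_mu))
  cat(sprintf("  QC / matrix / stability / ILC limit: +/-%g%%\n",
              x$qc_limit_pct))
  cat(sprintf("  LLOQ deviation limit: +/-%g%%\n", x$lloq_dev_pct))
  cat(sprintf("  crosstalk limits: %g%% (analyte channel), %g%% (IS channel)\n",
              x$crosstalk_analyte_max_pct, x$crosstalk_is_max_pct))
  cat(sprintf("  carryover limit: %g%%; minimal S/N: %g; dilution factor: %g\n",
              x$carryover_max_pct, x$sn_min, x$dilution_factor))
  invisible(x)
}
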