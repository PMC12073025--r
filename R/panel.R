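#' Default caftor analyte panel
#'
#' Concentration design of the shipped seven-analyte CFTR-modulator panel:
#' six calibrator levels, five validation QC levels and three routine QC
#' levels per analyte, in ug/mL. Any user-defined panel with the same columns
#' can be passed wherever a panel is accepted.
#'
#' @param role optional filter: one of `"cal"`, `"qc_validation"`,
#'   `"qc_routine"`; default returns all rows.
#' @return data.frame with columns `analyte`, `role`, `level`, `conc_ug_ml`.
#' @examples
#' head(caftor_panel("cal"))
#' @export
caftor_panel <- function(role = NULL) {
  path <- system.file("extdata", "caftor_panel_concentrations.csv",
                      package = "accuprofile", mustWork = TRUE)
  panel <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(role)) {
    role <- match.arg(role, c("cal", "qc_validation", "qc_routine"))
    panel <- panel[panel$role == role, , drop = FALSE]
    rownames(panel) <- NULL
  }
  panel
}

#' Printed validation summary of the caftor panel
#'
#' Per-analyte, per-level trueness and precision of the shipped caftor panel
#' (five QC levels each): trueness in percent of nominal with the published
#' interval half-width, repeatability and intermediate precision as CV%.
#' Used as the worked example for reconstructing accuracy profiles from
#' summary statistics alone.
#'
#' @return data.frame with columns `analyte`, `conc_ug_ml`, `trueness_pct`,
#'   `trueness_pm_pct`, `repeatability_pct`, `intermediate_precision_pct`.
#' @export
caftor_validation_summary <- function() {
  path <- system.file("extdata", "caftor_validation_summary.csv",
                      package = "accuprofile", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
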