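## End-to-end orchestration: generate or ingest a dataset, select the
## calibration model, build accuracy profiles, run every applicable check,
## and assemble the report. Also the routine-use path: batch QC acceptance
## and patient-sample quantification.

#' Run a full validation campaign
#'
#' Executes calibration model selection, accuracy profiling and every check
#' for which the dataset contains records (stability, matrix lots, dilution
#' QCs), per analyte. Either pass a dataset or a seed: with a seed alone, a
#' synthetic validation dataset is generated from
#' [default_synthetic_truth()] so the whole pipeline runs from a single
#' integer.
#'
#' @param measurements a `measurements` table (or path readable by
#'   [read_measurements()]), or `NULL` to generate synthetically.
#' @param seed integer seed for the synthetic path.
#' @param config a [validation_config()].
#' @param truth optional [synthetic_truth()] overriding the default for the
#'   synthetic path.
#' @param panel concentration design for the synthetic path.
#' @param candidates candidate model list for
#'   [select_calibration_model()]; a single-spec list skips selection.
#' @param design validation design counts for the synthetic path.
#' @param verbose emit stage-level messages.
#' @return a `validation_report`; its `overall_passed` flag reflects the
#'   campaign verdict.
#' @export
run_validation <- function(measurements = NULL, seed = NULL,
                           config = validation_config(),
                           truth = NULL, panel = caftor_panel(),
                           candidates = default_candidates(),
                           design = list(cal_replicates = 2, p = 3, n = 3),
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(measurements)) {
    if (is.null(seed) && is.null(truth)) {
      stop("supply a dataset, a seed, or a synthetic truth", call. = FALSE)
    }
    if (is.null(truth)) truth <- default_synthetic_truth(seed)
    say("generating synthetic validation dataset (seed %d)", truth$seed)
    measurements <- generate_validation_dataset(truth, design, panel)
  } else if (is.character(measurements)) {
    say("reading %s", measurements)
    measurements <- read_measurements(measurements)
  }
  m <- as_measurements(measurements)

  analytes <- unique(m$analyte)
  blocks <- list()
  for (a in analytes) {
    ma <- m[m$analyte == a, , drop = FALSE]
    cal <- ma[ma$role == "calibrator", , drop = FALSE]
    qc <- ma[ma$role == "qc", , drop = FALSE]
    if (!nrow(cal)) {
      say("analyte %s: no calibrators, skipped", a)
      next
    }
    block <- list(checks = list())
    if (nrow(qc) && length(candidates) >= 2L) {
      say("analyte %s: selecting calibration model (%d candidates)",
          a, length(candidates))
      sel <- select_calibration_model(cal, qc, candidates, config)
      fit <- sel$fits[[sel$chosen]]
      block$calibration <- fit
      block$model_selection <- sel$ranking
      block$profile <- sel$profiles[[sel$chosen]]
      block$levels <- block$profile$levels
    } else {
      spec <- if (length(candidates)) candidates[[1L]] else
        calibration_spec()
      fit <- fit_calibration(cal, spec)
      block$calibration <- fit
      if (nrow(qc)) {
        back <- back_calculate_measurements(qc, fit)
        block$levels <- summarize_levels(
          data.frame(nominal = back$nominal_ug_ml, day = back$day,
                     conc = back$conc_back_ug_ml), config = config)
        block$profile <- build_accuracy_profile(block$levels, config, a)
      } else {
        say("analyte %s: no QCs, calibration-only report", a)
      }
    }
    stab <- ma[ma$role == "stability", , drop = FALSE]
    if (nrow(stab)) {
      block$checks <- c(block$checks,
                        stability_assessment(stab, config, fit = fit))
    }
    lots <- ma[ma$role == "matrix_lot", , drop = FALSE]
    if (nrow(lots) && length(unique(lots$lot)) >= 2L) {
      block$checks$matrix_effect <- matrix_effect_quant(lots, fit, config)
    }
    dil <- ma[ma$role == "dilution_qc", , drop = FALSE]
    if (nrow(dil)) {
      block$checks$dilution <- dilution_integrity(dil, fit, config)
    }
    blocks[[a]] <- block
  }
  if (!length(blocks)) stop("no analyte could be processed", call. = FALSE)
  report <- validation_report(blocks, config)
  say("overall: %s", if (report$overall_passed) "PASS" else "FAIL")
  report
}

#' Quantify patient samples against a calibration
#'
#' The routine-use path: the batch is accepted when every routine QC level's
#' mean deviation from nominal stays within the QC limit; each patient
#' response ratio is back-calculated, range flags are applied against the
#' validated LLOQ/ULOQ, and a declared dilution factor is multiplied back
#' in. Concentrations below the LLOQ are reported as `NA` with the
#' `below_lloq` flag raised. A failed batch does not suppress results, but
#' every row carries `qc_batch_passed = FALSE` and a warning is emitted.
#'
#' @param patients `measurements` with role `"patient"`; optional `dilution`
#'   column.
#' @param fit the batch `calibration_fit`.
#' @param batch_qcs `measurements` with role `"qc"`: the routine QCs of the
#'   batch (three levels).
#' @param profile the analyte's validated `accuracy_profile` (supplies
#'   LLOQ/ULOQ).
#' @param config a [validation_config()].
#' @return data.frame of class `patient_result`: `analyte`, `conc_ug_ml`,
#'   `below_lloq`, `above_uloq`, `diluted`, `qc_batch_passed`.
#' @export
quantify_patients <- function(patients, fit, batch_qcs, profile,
                              config = validation_config()) {
  qc <- as_measurements(batch_qcs)
  qc <- qc[qc$role == "qc", , drop = FALSE]
  if (length(unique(qc$nominal_ug_ml)) < 3L) {
    stop("batch QCs at three levels are required", call. = FALSE)
  }
  qc_back <- back_calculate(fit, response_ratio(qc))
  qc_dev <- (qc_back - qc$nominal_ug_ml) / qc$nominal_ug_ml * 100
  level_dev <- tapply(qc_dev, qc$nominal_ug_ml, mean)
  qc_ok <- all(abs(level_dev) <= config$qc_limit_pct)
  if (!qc_ok) {
    warning(sprintf(
      "batch QC FAILED: level deviation(s) %s%% exceed +/-%g%%; results flagged",
      paste(formatC(level_dev[abs(level_dev) > config$qc_limit_pct],
                    format = "f", digits = 1), collapse = ", "),
      config$qc_limit_pct), call. = FALSE)
  }

  pts <- as_measurements(patients)
  pts <- pts[pts$role == "patient", , drop = FALSE]
  if (!nrow(pts)) stop("no patient records", call. = FALSE)
  ratio <- response_ratio(pts)
  lloq_ratio <- predict(fit, profile$lloq)
  uloq_ratio <- predict(fit, profile$uloq)

  rows <- lapply(seq_len(nrow(pts)), function(i) {
    reading <- tryCatch(back_calculate(fit, ratio[i]), error = function(e) {
      ## classify out-of-window readings by their response
      if (ratio[i] < lloq_ratio) -Inf else if (ratio[i] > uloq_ratio) Inf
      else NA_real_
    })
    dil <- pts$dilution[i]
    diluted <- !is.na(dil) && dil > 1
    below <- (!is.na(reading) && reading < profile$lloq) ||
      identical(reading, -Inf)
    above <- (!is.na(reading) && is.finite(reading) &&
                reading > profile$uloq) || identical(reading, Inf)
    conc <- if (below || !is.finite(reading)) NA_real_ else {
      reading * if (diluted) dil else 1
    }
    data.frame(analyte = pts$analyte[i], conc_ug_ml = conc,
               below_lloq = below, above_uloq = above, diluted = diluted,
               qc_batch_passed = qc_ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("patient_result", "data.frame")
  out
}
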