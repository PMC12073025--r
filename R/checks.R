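## Pass/fail acceptance computations: selectivity, crosstalk, carryover,
## quantitative matrix effect, stability, freeze-thaw, dilution integrity,
## inter-laboratory comparison, signal-to-noise and the dilution-based LOD.
##
## Boundary semantics: limits are inclusive for <=-type criteria, except
## selectivity where the guideline phrases the limits strictly ("<20 %",
## "<5 %") and the strict inequality is honored.

## verdicts compare the statistic rounded at 1e-9 so that inclusive
## boundaries (e.g. a deviation of exactly 15 %) are robust to
## floating-point representation of the inputs
pct_cmp <- function(statistic_pct, threshold_pct, comparison) {
  s <- round(statistic_pct, 9)
  switch(comparison,
         abs_le = abs(s) <= threshold_pct,
         le = s <= threshold_pct,
         lt = s < threshold_pct,
         ge = s >= threshold_pct)
}

new_check_result <- function(check_name, analyte_id, statistic_pct,
                             threshold_pct, comparison = c("abs_le", "le",
                                                           "lt", "ge"),
                             detail = NULL) {
  comparison <- match.arg(comparison)
  passed <- pct_cmp(statistic_pct, threshold_pct, comparison)
  structure(list(check_name = check_name, analyte_id = analyte_id,
                 statistic_pct = statistic_pct,
                 threshold_pct = threshold_pct, comparison = comparison,
                 passed = passed, detail = detail),
            class = "check_result")
}

#' @export
print.check_result <- function(x, ...) {
  cat(sprintf("[%s] %s: statistic %.2f%% vs limit %s%g%% -> %s\n",
              if (x$passed) "PASS" else "FAIL", x$check_name,
              x$statistic_pct,
              switch(x$comparison, abs_le = "+/-", le = "<=", lt = "<",
                     ge = ">="),
              x$threshold_pct,
              if (x$passed) "pass" else "fail"))
  if (!is.null(x$detail) && is.data.frame(x$detail)) {
    print.data.frame(format(x$detail, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Selectivity of blank matrix lots
#'
#' Per blank, the analyte-channel response as a percentage of the lowest
#' calibrator's analyte area and the IS-channel response as a percentage of
#' the reference IS area. Interference is negligible when all blanks stay
#' strictly below the two limits (by default 20 % and 5 %).
#'
#' @param blanks `measurements` with a blank role; their `analyte_area` and
#'   `is_area` columns are the two channel responses (zero allowed).
#' @param cal1_analyte_area analyte-channel area of the lowest calibrator.
#' @param is_area_ref reference internal-standard area.
#' @param config a [validation_config()].
#' @return a `check_result`; `detail` has one row per blank with both
#'   channel percentages.
#' @export
selectivity_check <- function(blanks, cal1_analyte_area, is_area_ref,
                              config = validation_config()) {
  b <- as_measurements(blanks)
  b <- b[b$role %in% c("blank", "double_blank"), , drop = FALSE]
  if (!nrow(b)) stop("no blank records", call. = FALSE)
  if (!(cal1_analyte_area > 0) || !(is_area_ref > 0)) {
    stop("reference areas must be positive", call. = FALSE)
  }
  analyte_pct <- ifelse(is.na(b$analyte_area), 0, b$analyte_area) /
    cal1_analyte_area * 100
  is_pct <- ifelse(is.na(b$is_area), 0, b$is_area) / is_area_ref * 100
  detail <- data.frame(analyte = b$analyte, lot = b$lot,
                       analyte_channel_pct = analyte_pct,
                       is_channel_pct = is_pct,
                       passed = pct_cmp(analyte_pct,
                                        config$crosstalk_analyte_max_pct,
                                        "lt") &
                         pct_cmp(is_pct, config$crosstalk_is_max_pct, "lt"))
  res <- new_check_result("selectivity", unique(b$analyte)[1],
                          max(analyte_pct),
                          config$crosstalk_analyte_max_pct,
                          comparison = "lt", detail = detail)
  ## both channels must clear their own strict limit
  res$passed <- res$passed &&
    all(pct_cmp(is_pct, config$crosstalk_is_max_pct, "lt"))
  res
}

#' Crosstalk between analyte and internal-standard channels
#'
#' Quantifies channel bleed with two dedicated injections: a blank
#' precipitated with the IS solution (CAL0 with IS) read in the analyte
#' channel against CAL1's analyte area (limit 20 %), and the highest
#' calibrator precipitated without IS (CAL6 without IS) read in the IS
#' channel against CAL1's IS area (limit 5 %). Both limits are inclusive.
#'
#' @param cal0_with_is single-row `measurements`: blank + IS injection.
#' @param cal6_without_is single-row `measurements`: top calibrator without
#'   IS; its `is_area` column holds the IS-channel response (zero allowed
#'   for blank-type roles).
#' @param cal1 single-row `measurements`: lowest calibrator with IS.
#' @param config a [validation_config()].
#' @return list of two `check_result`s: `is_in_analyte` and
#'   `analyte_in_is`.
#' @export
crosstalk_check <- function(cal0_with_is, cal6_without_is, cal1,
                            config = validation_config()) {
  get1 <- function(x, what) {
    if (is.null(x) || !nrow(as.data.frame(x))) {
      stop("missing injection: ", what, call. = FALSE)
    }
    as.data.frame(x)[1L, , drop = FALSE]
  }
  c0 <- get1(cal0_with_is, "CAL0 with IS")
  c6 <- get1(cal6_without_is, "CAL6 without IS")
  c1 <- get1(cal1, "CAL1")
  if (!(c1$analyte_area > 0) || is.na(c1$is_area) || !(c1$is_area > 0)) {
    stop("CAL1 areas must be positive", call. = FALSE)
  }
  r1 <- ifelse(is.na(c0$analyte_area), 0, c0$analyte_area) /
    c1$analyte_area * 100
  r2 <- ifelse(is.na(c6$is_area), 0, c6$is_area) / c1$is_area * 100
  list(
    is_in_analyte = new_check_result("crosstalk_is_in_analyte",
                                     c1$analyte, r1,
                                     config$crosstalk_analyte_max_pct, "le"),
    analyte_in_is = new_check_result("crosstalk_analyte_in_is",
                                     c1$analyte, r2,
                                     config$crosstalk_is_max_pct, "le")
  )
}

#' Carryover in blanks following a high-concentration injection
#'
#' The largest blank analyte area as a percentage of CAL1's analyte area,
#' against the carryover limit (inclusive; default 20 %).
#'
#' @param blank_after_high `measurements` of the blank injections (typically
#'   three) following the top calibrator.
#' @param cal1 single-row `measurements` of the lowest calibrator.
#' @param config a [validation_config()].
#' @return a `check_result` with per-blank detail.
#' @export
carryover_check <- function(blank_after_high, cal1,
                            config = validation_config()) {
  b <- as.data.frame(blank_after_high)
  if (!nrow(b)) stop("need at least one blank injection", call. = FALSE)
  c1 <- as.data.frame(cal1)[1L, , drop = FALSE]
  if (!(c1$analyte_area > 0)) stop("CAL1 analyte area must be positive",
                                   call. = FALSE)
  pct <- ifelse(is.na(b$analyte_area), 0, b$analyte_area) /
    c1$analyte_area * 100
  new_check_result("carryover", c1$analyte, max(pct),
                   config$carryover_max_pct, "le",
                   detail = data.frame(injection = seq_along(pct),
                                       carryover_pct = pct))
}

#' Quantitative matrix effect across independent lots
#'
#' Back-calculates every lot x level injection against the calibration fit
#' and reports the recovery deviation from nominal. The matrix effect is
#' negligible when every deviation stays within the QC limit (inclusive;
#' default +/-15 %). A lot missing a level is flagged in the detail, not
#' fatal.
#'
#' @param lot_panel `measurements` with role `"matrix_lot"` over >= 2 lots.
#' @param fit a `calibration_fit`.
#' @param config a [validation_config()].
#' @return a `check_result`; `detail` has one row per lot x level.
#' @export
matrix_effect_quant <- function(lot_panel, fit,
                                config = validation_config()) {
  m <- as_measurements(lot_panel)
  m <- m[m$role == "matrix_lot", , drop = FALSE]
  if (!nrow(m)) stop("no matrix-lot records", call. = FALSE)
  lots <- unique(m$lot)
  if (length(lots) < 2L) stop("need at least two matrix lots", call. = FALSE)
  levels <- sort(unique(m$nominal_ug_ml))
  expected <- expand.grid(lot = lots, nominal_ug_ml = levels,
                          stringsAsFactors = FALSE)
  present <- paste(m$lot, m$nominal_ug_ml)
  missing <- expected[!paste(expected$lot, expected$nominal_ug_ml) %in%
                        present, , drop = FALSE]
  back <- back_calculate(fit, response_ratio(m))
  dev <- (back - m$nominal_ug_ml) / m$nominal_ug_ml * 100
  detail <- data.frame(lot = m$lot, nominal_ug_ml = m$nominal_ug_ml,
                       back_ug_ml = back, deviation_pct = dev,
                       passed = pct_cmp(dev, config$qc_limit_pct, "abs_le"))
  res <- new_check_result("matrix_effect", unique(m$analyte)[1],
                          dev[which.max(abs(dev))], config$qc_limit_pct,
                          "abs_le", detail = detail)
  if (nrow(missing)) {
    res$missing_cells <- missing
    warning(sprintf("%d lot x level cell(s) missing from the matrix panel",
                    nrow(missing)), call. = FALSE)
  }
  res
}

## deviations of measured concentrations from nominal, per record
.conc_or_backcalc <- function(m, fit, what) {
  if ("conc_back_ug_ml" %in% names(m)) return(m$conc_back_ug_ml)
  if (is.null(fit)) {
    stop(sprintf("%s: supply a calibration fit or a conc_back_ug_ml column",
                 what), call. = FALSE)
  }
  back_calculate(fit, response_ratio(m))
}

#' Bench-top / short-term stability assessment
#'
#' Per storage condition (matrix x temperature) and timepoint, the mean
#' deviation of the measured concentrations from nominal across the QC
#' levels. Deviations are computed against the nominal concentration (the
#' t = 0 target), and a condition passes up to the last timepoint at which
#' the mean deviation stays within the limit (inclusive; default +/-15 %).
#'
#' @param series `measurements` with role `"stability"` (columns `matrix`,
#'   `temperature`, `time_h`); `t = 0` must be present per condition.
#' @param config a [validation_config()].
#' @param fit optional `calibration_fit` used to back-calculate areas; not
#'   needed if the series already carries `conc_back_ug_ml`.
#' @return list of `check_result`s, one per condition, each with per
#'   timepoint detail and a `longest_passing_h` element.
#' @export
stability_assessment <- function(series, config = validation_config(),
                                 fit = NULL) {
  m <- as_measurements(series)
  m <- m[m$role == "stability", , drop = FALSE]
  if (!nrow(m)) stop("no stability records", call. = FALSE)
  m$conc_back_ug_ml <- .conc_or_backcalc(m, fit, "stability_assessment")
  m$dev_pct <- (m$conc_back_ug_ml - m$nominal_ug_ml) / m$nominal_ug_ml * 100
  key <- paste(m$matrix, m$temperature, sep = " / ")
  out <- list()
  for (cond in unique(key)) {
    sub <- m[key == cond, , drop = FALSE]
    if (!any(sub$time_h == 0)) {
      stop("missing t = 0 reference for condition ", cond, call. = FALSE)
    }
    agg <- aggregate(dev_pct ~ time_h, data = sub, FUN = mean)
    agg <- agg[order(agg$time_h), , drop = FALSE]
    agg$passed <- pct_cmp(agg$dev_pct, config$qc_limit_pct, "abs_le")
    run_ok <- cumprod(agg$passed) == 1
    longest <- if (any(run_ok)) max(agg$time_h[run_ok]) else NA_real_
    first_fail <- if (all(agg$passed)) NA_real_ else
      min(agg$time_h[!agg$passed])
    res <- new_check_result(paste0("stability: ", cond),
                            unique(sub$analyte)[1],
                            agg$dev_pct[which.max(abs(agg$dev_pct))],
                            config$qc_limit_pct, "abs_le", detail = agg)
    res$longest_passing_h <- longest
    res$first_failing_h <- first_fail
    out[[cond]] <- res
  }
  out
}

#' Freeze-thaw stability
#'
#' Mean deviation per freeze-thaw cycle relative to the cycle-0 reference
#' measurements, averaged across QC levels; all cycles must stay within the
#' limit (inclusive; default +/-15 %).
#'
#' @param cycles `measurements` with a `cycle` column; cycle 0 is the
#'   reference and must be present.
#' @param config a [validation_config()].
#' @param fit optional `calibration_fit` (see [stability_assessment()]).
#' @return a `check_result` with per-cycle detail.
#' @export
freeze_thaw_assessment <- function(cycles, config = validation_config(),
                                   fit = NULL) {
  m <- as_measurements(cycles)
  if (!nrow(m)) stop("no freeze-thaw records", call. = FALSE)
  if (!any(m$cycle == 0, na.rm = TRUE)) {
    stop("missing cycle-0 reference", call. = FALSE)
  }
  m$conc_back_ug_ml <- .conc_or_backcalc(m, fit, "freeze_thaw_assessment")
  ref <- aggregate(conc_back_ug_ml ~ nominal_ug_ml,
                   data = m[m$cycle == 0, ], FUN = mean)
  names(ref)[2] <- "ref_conc"
  mm <- merge(m[m$cycle > 0, ], ref, by = "nominal_ug_ml")
  mm$dev_pct <- (mm$conc_back_ug_ml - mm$ref_conc) / mm$ref_conc * 100
  agg <- aggregate(dev_pct ~ cycle, data = mm, FUN = mean)
  agg$passed <- pct_cmp(agg$dev_pct, config$qc_limit_pct, "abs_le")
  new_check_result("freeze_thaw", unique(m$analyte)[1],
                   agg$dev_pct[which.max(abs(agg$dev_pct))],
                   config$qc_limit_pct, "abs_le", detail = agg)
}

#' Dilution integrity
#'
#' Above-range QCs diluted into the validated range: the diluted reading is
#' back-calculated, multiplied by the dilution factor and compared with the
#' undiluted nominal. A diluted reading falling outside the calibration
#' range is an error (it defeats the purpose of the check). All per-lot
#' deviations must stay within the limit (inclusive; default +/-15 %).
#'
#' @param diluted_qcs `measurements` with role `"dilution_qc"`;
#'   `nominal_ug_ml` is the undiluted nominal and the optional `dilution`
#'   column the per-record factor (default `config$dilution_factor`).
#' @param fit a `calibration_fit`.
#' @param config a [validation_config()].
#' @return a `check_result` with per-lot detail.
#' @export
dilution_integrity <- function(diluted_qcs, fit,
                               config = validation_config()) {
  m <- as_measurements(diluted_qcs)
  m <- m[m$role == "dilution_qc", , drop = FALSE]
  if (!nrow(m)) stop("no dilution-QC records", call. = FALSE)
  factor <- ifelse(is.na(m$dilution), config$dilution_factor, m$dilution)
  if (any(factor <= 1)) stop("dilution factor must exceed 1", call. = FALSE)
  back <- back_calculate(fit, response_ratio(m))
  outside <- back < fit$range[1] | back > fit$range[2]
  if (any(outside)) {
    stop(sprintf("%d diluted reading(s) outside the validated range [%g, %g] ug/mL",
                 sum(outside), fit$range[1], fit$range[2]), call. = FALSE)
  }
  recovered <- back * factor
  dev <- (recovered - m$nominal_ug_ml) / m$nominal_ug_ml * 100
  new_check_result("dilution_integrity", unique(m$analyte)[1],
                   dev[which.max(abs(dev))], config$qc_limit_pct, "abs_le",
                   detail = data.frame(lot = m$lot, dilution = factor,
                                       diluted_ug_ml = back,
                                       recovered_ug_ml = recovered,
                                       deviation_pct = dev,
                                       passed = pct_cmp(dev,
                                                        config$qc_limit_pct,
                                                        "abs_le")))
}

#' Inter-laboratory comparison
#'
#' Per-sample bias of an external laboratory against the home laboratory,
#' `(external - home) / home * 100`, with the acceptance limit applied
#' inclusively (default +/-15 %). Unpaired samples (missing on either side)
#' are flagged and excluded from the summary.
#'
#' @param home_values home-laboratory concentrations (> 0).
#' @param external_values external-laboratory concentrations, paired by
#'   position (or by `sample_id`).
#' @param config a [validation_config()].
#' @param sample_id optional sample labels.
#' @param lab optional laboratory label per pair (for the per-lab summary).
#' @return a `check_result`; `detail` has one row per pair, and the
#'   `lab_summary` element the mean bias per laboratory.
#' @export
ilc_compare <- function(home_values, external_values,
                        config = validation_config(), sample_id = NULL,
                        lab = NULL) {
  stopifnot(length(home_values) == length(external_values))
  if (is.null(sample_id)) sample_id <- paste0("S", seq_along(home_values))
  if (is.null(lab)) lab <- rep("external", length(home_values))
  paired <- !is.na(home_values) & !is.na(external_values)
  if (!any(paired)) stop("no complete sample pairs", call. = FALSE)
  if (any(home_values[paired] <= 0)) {
    stop("home-laboratory values must be positive", call. = FALSE)
  }
  bias <- rep(NA_real_, length(home_values))
  bias[paired] <- (external_values[paired] - home_values[paired]) /
    home_values[paired] * 100
  detail <- data.frame(sample_id = sample_id, lab = lab,
                       home = home_values, external = external_values,
                       bias_pct = bias, paired = paired,
                       passed = !is.na(bias) &
                         pct_cmp(bias, config$qc_limit_pct, "abs_le"))
  lab_summary <- aggregate(bias_pct ~ lab, data = detail[paired, ],
                           FUN = mean)
  names(lab_summary)[2] <- "mean_bias_pct"
  worst <- bias[paired][which.max(abs(bias[paired]))]
  res <- new_check_result("ilc", NA_character_, worst,
                          config$qc_limit_pct, "abs_le", detail = detail)
  res$lab_summary <- lab_summary
  res
}

#' Signal-to-noise ratio of a chromatographic trace
#'
#' `(max in peak window - baseline mean) / baseline SD`. A perfectly flat
#' baseline (zero SD) returns `Inf` with a warning — an above-threshold
#' sentinel.
#'
#' @param trace a `chromatogram` (from [generate_chromatogram()]) or a
#'   numeric intensity vector.
#' @param peak_window,baseline_window index vectors into the trace; default
#'   to the windows carried by the `chromatogram` object. Must be disjoint;
#'   the baseline needs >= 20 points.
#' @return the estimated S/N (scalar).
#' @export
signal_to_noise <- function(trace, peak_window = NULL,
                            baseline_window = NULL) {
  if (inherits(trace, "chromatogram")) {
    intensity <- trace$intensity
    if (is.null(peak_window)) peak_window <- trace$peak_window
    if (is.null(baseline_window)) baseline_window <- trace$baseline_window
  } else {
    intensity <- as.numeric(trace)
  }
  stopifnot(!is.null(peak_window), !is.null(baseline_window))
  if (length(intersect(peak_window, baseline_window))) {
    stop("peak and baseline windows must be disjoint", call. = FALSE)
  }
  if (length(baseline_window) < 20L) {
    stop("baseline window needs at least 20 points", call. = FALSE)
  }
  noise <- sd(intensity[baseline_window])
  ## peak amplitude from a lightly smoothed trace (5-point moving average
  ## when the sampling density permits): taking the raw maximum rides the
  ## upper tail of the noise and biases S/N upward
  k <- if (length(intensity) >= 500L) 5L else 1L
  peak_int <- intensity[peak_window]
  if (k > 1L) {
    sm <- stats::filter(peak_int, rep(1 / k, k), sides = 2)
    peak_int <- sm[!is.na(sm)]
  }
  signal <- max(peak_int) - mean(intensity[baseline_window])
  if (noise <= 1e-9 * max(abs(signal), 1)) {
    warning("zero baseline SD: reporting infinite S/N", call. = FALSE)
    return(Inf)
  }
  signal / noise
}

#' Limit of detection from a serial dilution of the lowest calibrator
#'
#' Given signal-to-noise measurements of increasing dilutions of CAL1, the
#' LOD is the smallest concentration in the series whose S/N still meets
#' `config$sn_min`. If no member qualifies, `NA` is returned (a no-LOD
#' sentinel).
#'
#' @param cal1_conc concentration of CAL1 (ug/mL).
#' @param dilution_series data.frame with columns `factor` (increasing
#'   dilution factors) and `sn`.
#' @param config a [validation_config()].
#' @return list with `lod_ug_ml` (or `NA`), its `sn`, and the evaluated
#'   series.
#' @export
lod_from_dilution <- function(cal1_conc, dilution_series,
                              config = validation_config()) {
  stopifnot(is.data.frame(dilution_series),
            all(c("factor", "sn") %in% names(dilution_series)),
            nrow(dilution_series) >= 1L, cal1_conc > 0)
  if (is.unsorted(dilution_series$factor, strictly = TRUE)) {
    stop("dilution factors must be strictly increasing", call. = FALSE)
  }
  series <- data.frame(factor = dilution_series$factor,
                       conc_ug_ml = cal1_conc / dilution_series$factor,
                       sn = dilution_series$sn)
  ok <- series$sn >= config$sn_min
  if (!any(ok)) {
    return(list(lod_ug_ml = NA_real_, sn = NA_real_, series = series))
  }
  i <- which(ok)[which.min(series$conc_ug_ml[ok])]
  list(lod_ug_ml = series$conc_ug_ml[i], sn = series$sn[i], series = series)
}
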