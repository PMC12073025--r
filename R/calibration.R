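## Calibration modelling and inverse prediction.
##
## Models are fitted by (weighted) least squares of the transformed response
## ratio on the transformed concentration. Under the log-log transform the
## default weighting is unit weighting, since the transform itself
## stabilizes the multiplicative variance typical of LC-MS/MS responses.
## Logs are natural logs; fit quality is base-invariant.

#' Specify a candidate calibration model
#'
#' @param family `"linear"` or `"quadratic"` (in the transformed
#'   concentration).
#' @param transform `"log_log"` (fit `log(ratio)` on `log(C)`) or `"none"`.
#' @param weighting `"unit"`, `"inverse_x"` (1/C) or `"inverse_x2"` (1/C^2),
#'   applied on the fitting scale.
#' @param levels_used optional subset of calibrator concentrations to use;
#'   `NULL` uses all.
#' @return an object of class `calibration_spec`.
#' @export
calibration_spec <- function(family = c("quadratic", "linear"),
                             transform = c("log_log", "none"),
                             weighting = c("unit", "inverse_x", "inverse_x2"),
                             levels_used = NULL) {
  spec <- structure(
    list(family = match.arg(family), transform = match.arg(transform),
         weighting = match.arg(weighting), levels_used = levels_used),
    class = "calibration_spec")
  spec
}

#' Default candidate model list
#'
#' The model families routinely compared during method validation: quadratic
#' and linear fits on the log-log scale (unit weights) and a 1/x^2-weighted
#' linear fit on the raw scale.
#'
#' @return list of [calibration_spec()] objects.
#' @export
default_candidates <- function() {
  list(
    quadratic_log_log = calibration_spec("quadratic", "log_log", "unit"),
    linear_log_log = calibration_spec("linear", "log_log", "unit"),
    linear_weighted = calibration_spec("linear", "none", "inverse_x2")
  )
}

#' Fit a calibration model
#'
#' Weighted least squares of the (transformed) analyte/IS response ratio on
#' the (transformed) nominal concentration. The coefficient of determination
#' is computed on the fitting scale; every calibrator is back-calculated by
#' inverse prediction and its deviation from nominal reported, together with
#' the slope of back-calculated versus nominal concentration (the linearity
#' diagnostic, ideally 1).
#'
#' @param calibrators a `measurements` table; only rows with role
#'   `"calibrator"` are used.
#' @param spec a [calibration_spec()].
#' @return an object of class `calibration_fit` with elements `spec`,
#'   `coeffs` (`a`, `b`, `c`; `c = 0` for linear fits), `r_squared`,
#'   `back_calc` (per-calibrator data.frame), `linearity_slope` and `range`
#'   (lowest/highest fitted level).
#' @export
fit_calibration <- function(calibrators, spec = calibration_spec()) {
  m <- as_measurements(calibrators)
  m <- m[m$role == "calibrator", , drop = FALSE]
  if (!nrow(m)) stop("no calibrator records", call. = FALSE)
  if (!is.null(spec$levels_used)) {
    m <- m[m$nominal_ug_ml %in% spec$levels_used, , drop = FALSE]
  }
  conc <- m$nominal_ug_ml
  ratio <- response_ratio(m)
  n_levels <- length(unique(conc))
  needed <- if (spec$family == "quadratic") 4L else 3L
  if (n_levels < needed) {
    stop(sprintf("%s fit needs >= %d distinct calibrator levels, got %d",
                 spec$family, needed, n_levels), call. = FALSE)
  }
  if (spec$transform == "log_log" && any(ratio <= 0)) {
    bad <- which(ratio <= 0)[1L]
    stop(sprintf(
      "nonpositive response ratio under log-log transform (analyte %s, level %g, day %d, replicate %d)",
      m$analyte[bad], m$nominal_ug_ml[bad], m$day[bad], m$replicate[bad]),
      call. = FALSE)
  }
  x <- if (spec$transform == "log_log") log(conc) else conc
  y <- if (spec$transform == "log_log") log(ratio) else ratio
  w <- switch(spec$weighting,
              unit = rep(1, length(conc)),
              inverse_x = 1 / conc,
              inverse_x2 = 1 / conc^2)
  model <- if (spec$family == "quadratic") {
    lm(y ~ x + I(x^2), weights = w)
  } else {
    lm(y ~ x, weights = w)
  }
  cf <- coef(model)
  coeffs <- c(a = unname(cf[1]), b = unname(cf[2]),
              c = if (spec$family == "quadratic") unname(cf[3]) else 0)
  ## weighted R^2 on the fitting scale, computed directly (summary.lm warns
  ## on the exact fits used as fixtures)
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * model$residuals^2) / sum(w * (y - ybar)^2)

  fit <- structure(
    list(spec = spec, coeffs = coeffs, r_squared = r2,
         range = range(conc), analyte = unique(m$analyte),
         back_calc = NULL, linearity_slope = NA_real_),
    class = "calibration_fit")
  back <- back_calculate(fit, ratio)
  fit$back_calc <- data.frame(
    nominal_ug_ml = conc, ratio = ratio, back_ug_ml = back,
    deviation_pct = (back - conc) / conc * 100)
  fit$linearity_slope <- unname(coef(lm(back ~ conc))[2])
  fit
}

#' Predicted response ratio at a concentration
#'
#' @param object a `calibration_fit`.
#' @param conc concentration(s) in ug/mL.
#' @param ... unused.
#' @return predicted analyte/IS response ratio(s).
#' @export
predict.calibration_fit <- function(object, conc, ...) {
  k <- object$coeffs
  x <- if (object$spec$transform == "log_log") log(conc) else conc
  y <- k[["a"]] + k[["b"]] * x + k[["c"]] * x^2
  if (object$spec$transform == "log_log") exp(y) else y
}

#' Back-calculate a concentration by inverse prediction
#'
#' Inverts the fitted response model. For quadratic fits the quadratic in
#' the (transformed) concentration is solved exactly; the root lying inside
#' `[0.5 * lowest level, 2 * highest level]` is returned. No root in that
#' window is an out-of-range error; two roots in the window is an ambiguity
#' error (reported, never silently resolved).
#'
#' @param fit a `calibration_fit`.
#' @param ratio analyte/IS response ratio(s); must be positive for log-log
#'   fits.
#' @return concentration(s) in ug/mL.
#' @export
back_calculate <- function(fit, ratio) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$spec$transform == "log_log" && any(ratio <= 0, na.rm = TRUE)) {
    stop("response ratio must be positive for a log-log fit", call. = FALSE)
  }
  k <- fit$coeffs
  lo <- 0.5 * fit$range[1]
  hi <- 2 * fit$range[2]
  y <- if (fit$spec$transform == "log_log") log(ratio) else ratio

  solve_one <- function(yi) {
    if (is.na(yi)) return(NA_real_)
    if (k[["c"]] == 0) {
      xi <- (yi - k[["a"]]) / k[["b"]]
      ci <- if (fit$spec$transform == "log_log") exp(xi) else xi
      if (ci < lo || ci > hi) {
        stop(sprintf("back-calculated concentration %.6g outside the calibration window [%.6g, %.6g]",
                     ci, lo, hi), call. = FALSE)
      }
      return(ci)
    }
    disc <- k[["b"]]^2 - 4 * k[["c"]] * (k[["a"]] - yi)
    if (disc < 0) {
      stop("no real root: response outside the reachable range of the quadratic model",
           call. = FALSE)
    }
    ## numerically stable form: avoids cancellation when |c| is tiny
    q <- -(k[["b"]] + sign(k[["b"]]) * sqrt(disc)) / 2
    roots <- c(q / k[["c"]], (k[["a"]] - yi) / q)
    cand <- if (fit$spec$transform == "log_log") exp(roots) else roots
    inside <- cand[cand >= lo & cand <= hi]
    if (length(inside) == 0L) {
      stop(sprintf("no root inside the calibration window [%.6g, %.6g] (candidates %.6g, %.6g)",
                   lo, hi, cand[1], cand[2]), call. = FALSE)
    }
    if (length(inside) == 2L && abs(diff(inside)) > 1e-9 * max(abs(inside))) {
      stop(sprintf("ambiguous inversion: both roots (%.6g, %.6g) lie inside the calibration window",
                   inside[1], inside[2]), call. = FALSE)
    }
    inside[1]
  }
  vapply(y, solve_one, numeric(1))
}

#' @export
print.calibration_fit <- function(x, ...) {
  k <- x$coeffs
  cat(sprintf("Calibration fit (%s, %s, %s weighting)\n",
              x$spec$family, x$spec$transform, x$spec$weighting))
  cat(sprintf("  coefficients: a = %.6g, b = %.6g, c = %.6g\n",
              k[["a"]], k[["b"]], k[["c"]]))
  cat(sprintf("  R^2 = %.5f; linearity slope (back-calc vs nominal) = %.4f\n",
              x$r_squared, x$linearity_slope))
  cat(sprintf("  range: %.4g - %.4g ug/mL, %d calibrators\n",
              x$range[1], x$range[2], nrow(x$back_calc)))
  invisible(x)
}

#' Back-calculate a measurements table against a fit
#'
#' Convenience wrapper appending a `conc_back_ug_ml` column with the
#' inverse-predicted concentration of every record.
#'
#' @param measurements a `measurements` table.
#' @param fit a `calibration_fit`.
#' @return the table with `conc_back_ug_ml` appended.
#' @export
back_calculate_measurements <- function(measurements, fit) {
  m <- as_measurements(measurements)
  m$conc_back_ug_ml <- back_calculate(fit, response_ratio(m))
  m
}

#' Select the best calibration model by accuracy-profile metrics
#'
#' Fits every candidate to the calibrators, back-calculates the validation
#' QCs, builds the accuracy profile for each candidate and ranks by
#' (1) lowest achievable LLOQ, (2) narrowest mean total-error envelope of
#' the tolerance intervals — the mean of `max(|tol_low|, |tol_high|)`, i.e.
#' `|bias| + half-width`, so that a model cannot win by trading accuracy
#' for a tight but displaced interval — and (3) fewest model parameters as
#' the tie-break.
#'
#' @param calibrators calibrator `measurements`.
#' @param qc_measurements QC `measurements` (role `"qc"`) with a balanced
#'   day x replicate design per level.
#' @param candidates list of [calibration_spec()]; default
#'   [default_candidates()].
#' @param config a [validation_config()].
#' @return an object of class `model_selection`: list with `chosen` (name of
#'   the winning candidate), `ranking` (data.frame of metrics in rank
#'   order), `fits` and `profiles`.
#' @export
select_calibration_model <- function(calibrators, qc_measurements,
                                     candidates = default_candidates(),
                                     config = validation_config()) {
  if (length(candidates) < 2L) {
    stop("need at least two candidate models to select between", call. = FALSE)
  }
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate_", seq_along(candidates))
  }
  qc <- as_measurements(qc_measurements)
  qc <- qc[qc$role == "qc", , drop = FALSE]
  if (!nrow(qc)) stop("no QC records to rank candidates on", call. = FALSE)

  fits <- list(); profiles <- list(); rows <- list(); failures <- character(0)
  for (nm in names(candidates)) {
    res <- tryCatch({
      fit <- fit_calibration(calibrators, candidates[[nm]])
      back <- back_calculate_measurements(qc, fit)
      ls <- summarize_levels(
        data.frame(nominal = back$nominal_ug_ml, day = back$day,
                   conc = back$conc_back_ug_ml),
        config = config)
      prof <- build_accuracy_profile(ls, config,
                                     analyte_id = unique(qc$analyte)[1])
      list(fit = fit, prof = prof)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", nm, conditionMessage(res)))
      next
    }
    fits[[nm]] <- res$fit
    profiles[[nm]] <- res$prof
    lv <- res$prof$levels
    rows[[nm]] <- data.frame(
      candidate = nm,
      lloq = if (is.na(res$prof$lloq)) Inf else res$prof$lloq,
      mean_envelope_pct = mean(pmax(abs(lv$tol_low_pct),
                                    abs(lv$tol_high_pct))),
      mean_interval_width_pct = mean(lv$tol_high_pct - lv$tol_low_pct),
      n_params = if (candidates[[nm]]$family == "quadratic") 3L else 2L,
      r_squared = res$fit$r_squared, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("all candidate models failed to fit:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  ranking <- do.call(rbind, rows)
  ## round the envelope to avoid floating-point noise breaking exact ties
  ord <- order(ranking$lloq, round(ranking$mean_envelope_pct, 6),
               ranking$n_params)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(chosen = ranking$candidate[1L], ranking = ranking,
                 fits = fits, profiles = profiles, failures = failures),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Calibration model selection\n")
  cat("  chosen:", x$chosen, "\n")
  print.data.frame(x$ranking, row.names = FALSE, digits = 4)
  if (length(x$failures)) {
    cat("  failed candidates:\n   ", paste(x$failures, collapse = "\n    "),
        "\n")
  }
  invisible(x)
}
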