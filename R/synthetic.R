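## Synthetic validation data with known ground truth.
##
## Noise is applied on the concentration scale (so within- and between-day
## SDs read directly as CV% of nominal) and then mapped through the response
## model to peak areas; the internal standard area is held at a nominal
## constant. Day effects are drawn once per day and analyte and shared across
## levels (a common run effect), scaled by the level-specific between-day CV.

#' Ground truth for the synthetic-data generator
#'
#' @param calib_coeffs numeric `(a, b, c)` of the response model
#'   `log(ratio) = a + b*log(C) + c*log(C)^2` (natural logs; `c = 0` gives a
#'   power law, `a = 0, b = 1, c = 0` the identity `ratio = C`).
#' @param bias_pct systematic error in percent of nominal; scalar or one
#'   value per QC level (low to high).
#' @param s_within_pct within-day SD as percent of nominal; scalar or
#'   per-level.
#' @param s_between_pct between-day SD as percent of nominal; scalar or
#'   per-level.
#' @param matrix_factors `NULL` (no lot effects) or a data.frame with columns
#'   `lot`, `analyte_factor`, `is_factor`: multiplicative per-lot response
#'   factors, all positive.
#' @param decay_rate fractional loss per hour for stability series; scalar,
#'   or named by condition as `"<matrix>_<temperature>"` (e.g. `plasma_rt`).
#' @param carryover_frac fraction of the previous injection's area appearing
#'   in a subsequent blank, in `[0, 1)`.
#' @param is_area nominal internal-standard response (arbitrary units).
#' @param seed integer seed; generators seed the RNG with it when not `NULL`.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(calib_coeffs = c(a = 0, b = 1, c = 0),
                            bias_pct = 0,
                            s_within_pct = 0,
                            s_between_pct = 0,
                            matrix_factors = NULL,
                            decay_rate = 0,
                            carryover_frac = 0,
                            is_area = 1e5,
                            seed = NULL) {
  stopifnot(is.numeric(calib_coeffs), length(calib_coeffs) == 3L,
            all(is.finite(calib_coeffs)),
            all(s_within_pct >= 0), all(s_between_pct >= 0),
            all(decay_rate >= 0),
            length(carryover_frac) == 1L, carryover_frac >= 0,
            carryover_frac < 1, is_area > 0)
  if (!is.null(matrix_factors)) {
    stopifnot(is.data.frame(matrix_factors),
              all(c("lot", "analyte_factor", "is_factor") %in%
                    names(matrix_factors)),
              all(matrix_factors$analyte_factor > 0),
              all(matrix_factors$is_factor > 0))
  }
  structure(
    list(calib_coeffs = unname(calib_coeffs), bias_pct = bias_pct,
         s_within_pct = s_within_pct, s_between_pct = s_between_pct,
         matrix_factors = matrix_factors, decay_rate = decay_rate,
         carryover_frac = carryover_frac, is_area = is_area,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Default ground truth of the shipped fixture
#'
#' A saturating quadratic log-log response — the curvature is sized so that
#' the lack of fit of a straight line on the log-log scale reaches roughly
#' 10-20 % at the extremes of a hundred-fold calibration range, the regime
#' in which a quadratic term is genuinely warranted — and per-level error
#' magnitudes chosen to sit inside the precision ranges of the shipped
#' caftor validation summary (repeatability roughly 1-8 CV%, intermediate
#' precision 1-11 CV%), with more noise and bias at the low end of the
#' range, as is typical of trace-level LC-MS/MS.
#'
#' @param seed integer seed stored in the truth object.
#' @return a [synthetic_truth()].
#' @export
default_synthetic_truth <- function(seed = 20260925L) {
  synthetic_truth(
    calib_coeffs = c(a = 0, b = 1, c = -0.04),
    bias_pct = c(0.5, -2.0, 2.2, 2.9, -0.5),
    s_within_pct = c(4.5, 4.0, 3.5, 3.2, 3.0),
    s_between_pct = c(4.0, 3.5, 3.0, 2.5, 2.2),
    decay_rate = c(plasma_rt = 0.004, plasma_4C = 0.001,
                   whole_blood_rt = 0.006, whole_blood_4C = 0.002),
    carryover_frac = 0.001,
    seed = seed
  )
}

## response model: concentration -> analyte/IS ratio
conc_to_ratio <- function(truth, conc) {
  stopifnot(all(conc > 0))
  k <- truth$calib_coeffs
  lc <- log(conc)
  exp(k[1] + k[2] * lc + k[3] * lc^2)
}

recycle_levels <- function(x, n_levels, what) {
  if (length(x) == 1L) return(rep(x, n_levels))
  if (length(x) != n_levels) {
    stop(sprintf("%s must have length 1 or %d (one per QC level)",
                 what, n_levels), call. = FALSE)
  }
  x
}

#' Generate a complete synthetic validation dataset
#'
#' Emits calibrators (`cal_levels x cal_replicates`, single day) and QC
#' records (`qc_levels x p days x n replicates`) for every analyte of the
#' panel. The measured QC concentration is
#' `nominal * (1 + bias/100) * (1 + day_effect + residual)` with
#' `day_effect ~ N(0, s_between/100)` shared across levels within a day and
#' `residual ~ N(0, s_within/100)`; calibrators carry residual noise at the
#' mean within-day CV. Concentrations are mapped through the response model
#' to peak areas with the internal-standard area held constant.
#'
#' @param truth a [synthetic_truth()].
#' @param design list with `cal_replicates`, `p` (days) and `n` (replicates
#'   per day); defaults `list(cal_replicates = 2, p = 3, n = 3)`.
#' @param panel concentration design with columns `analyte`, `role`
#'   (`"cal"` / `"qc_validation"`), `level`, `conc_ug_ml`; defaults to
#'   [caftor_panel()].
#' @return a `measurements` table; reproducible for a given `truth$seed`.
#' @export
generate_validation_dataset <- function(truth,
                                        design = list(cal_replicates = 2,
                                                      p = 3, n = 3),
                                        panel = caftor_panel()) {
  stopifnot(inherits(truth, "synthetic_truth"),
            all(c("cal_replicates", "p", "n") %in% names(design)))
  cal_replicates <- as.integer(design$cal_replicates)
  p <- as.integer(design$p); n <- as.integer(design$n)
  stopifnot(cal_replicates >= 1L, p >= 1L, n >= 1L)
  if (any(panel$conc_ug_ml <= 0)) {
    stop("panel concentrations must be positive", call. = FALSE)
  }
  if (!is.null(truth$seed)) set.seed(truth$seed)

  out <- list()
  for (a in unique(panel$analyte)) {
    cal_conc <- sort(panel$conc_ug_ml[panel$analyte == a &
                                        panel$role == "cal"])
    qc_conc <- sort(panel$conc_ug_ml[panel$analyte == a &
                                       panel$role == "qc_validation"])
    n_lev <- length(qc_conc)
    bias <- recycle_levels(truth$bias_pct, n_lev, "bias_pct") / 100
    s_w <- recycle_levels(truth$s_within_pct, n_lev, "s_within_pct") / 100
    s_b <- recycle_levels(truth$s_between_pct, n_lev, "s_between_pct") / 100
    cal_cv <- mean(s_w)

    if (length(cal_conc)) {
      grid <- expand.grid(replicate = seq_len(cal_replicates),
                          conc = cal_conc)
      meas <- grid$conc * (1 + rnorm(nrow(grid), 0, cal_cv))
      if (any(meas <= 0)) stop("nonpositive concentration generated for calibrator",
                               call. = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        analyte = a, role = "calibrator", day = 1L,
        replicate = grid$replicate, nominal_ug_ml = grid$conc,
        analyte_area = conc_to_ratio(truth, meas) * truth$is_area,
        is_area = truth$is_area, stringsAsFactors = FALSE)
    }

    if (n_lev) {
      day_z <- rnorm(p)  # shared run effect, scaled per level below
      grid <- expand.grid(replicate = seq_len(n), day = seq_len(p),
                          level = seq_len(n_lev))
      nominal <- qc_conc[grid$level]
      meas <- nominal * (1 + bias[grid$level]) *
        (1 + day_z[grid$day] * s_b[grid$level] +
           rnorm(nrow(grid), 0, 1) * s_w[grid$level])
      if (any(meas <= 0)) {
        stop("nonpositive concentration generated for QC (noise too large)",
             call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        analyte = a, role = "qc", day = grid$day,
        replicate = grid$replicate, nominal_ug_ml = nominal,
        analyte_area = conc_to_ratio(truth, meas) * truth$is_area,
        is_area = truth$is_area, stringsAsFactors = FALSE)
    }
  }
  as_measurements(do.call(rbind, out))
}

#' Generate a stability time series
#'
#' Measured value at time `t` is `nominal * (1 - decay_rate * t) * (1 +
#' noise)` with noise at the mean within-day CV of the truth; `t = 0` is
#' unbiased by construction. Decay producing a nonpositive concentration is
#' clamped just above zero with a warning.
#'
#' @param truth a [synthetic_truth()]; `decay_rate` may be a named vector
#'   keyed `"<matrix>_<temperature>"`.
#' @param timepoints hours; must include 0.
#' @param conditions data.frame with columns `matrix` and `temperature`;
#'   defaults to plasma/whole blood at rt and 4C.
#' @param qc_levels concentrations (ug/mL) of the stability QCs; default the
#'   routine QC levels of `analyte` in the caftor panel.
#' @param analyte analyte id for the emitted records.
#' @return a `measurements` table with role `"stability"`.
#' @export
generate_stability_series <- function(truth,
                                      timepoints = c(0, 2, 4, 6, 24, 48, 72),
                                      conditions = expand.grid(
                                        matrix = c("plasma", "whole_blood"),
                                        temperature = c("rt", "4C"),
                                        stringsAsFactors = FALSE),
                                      qc_levels = NULL,
                                      analyte = "IVA") {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!any(timepoints == 0)) {
    stop("timepoints must include 0 (the reference)", call. = FALSE)
  }
  if (is.null(qc_levels)) {
    qp <- caftor_panel("qc_routine")
    qc_levels <- sort(qp$conc_ug_ml[qp$analyte == analyte])
  }
  stopifnot(length(qc_levels) >= 1L, all(qc_levels > 0))
  if (!is.null(truth$seed)) set.seed(truth$seed)
  cv <- mean(recycle_levels(truth$s_within_pct,
                            max(length(truth$s_within_pct), 1L),
                            "s_within_pct")) / 100

  decay_for <- function(mat, temp) {
    d <- truth$decay_rate
    if (length(d) == 1L && is.null(names(d))) return(unname(d))
    key <- paste(mat, temp, sep = "_")
    if (!key %in% names(d)) {
      stop("no decay_rate for condition ", key, call. = FALSE)
    }
    unname(d[[key]])
  }

  grid <- expand.grid(conc = qc_levels, time_h = sort(timepoints),
                      idx = seq_len(nrow(conditions)))
  mat <- conditions$matrix[grid$idx]
  temp <- conditions$temperature[grid$idx]
  decay <- mapply(decay_for, mat, temp)
  remaining <- 1 - decay * grid$time_h
  clamped <- remaining <= 0
  if (any(clamped)) {
    warning(sprintf("%d record(s) decayed to a nonpositive concentration; clamped",
                    sum(clamped)), call. = FALSE)
    remaining[clamped] <- 1e-6
  }
  meas <- grid$conc * remaining * (1 + rnorm(nrow(grid), 0, cv))
  meas[meas <= 0] <- grid$conc[meas <= 0] * 1e-6
  as_measurements(data.frame(
    analyte = analyte, role = "stability", day = 1L, replicate = 1L,
    nominal_ug_ml = grid$conc,
    analyte_area = conc_to_ratio(truth, meas) * truth$is_area,
    is_area = truth$is_area, matrix = mat, temperature = temp,
    time_h = grid$time_h, stringsAsFactors = FALSE))
}

#' Generate a matrix-lot panel
#'
#' One injection per lot and level; lot `l` scales the analyte area by its
#' `analyte_factor` and the IS area by its `is_factor`, emulating
#' lot-specific ionization suppression or enhancement. With equal factors
#' the analyte/IS ratio — and hence the back-calculated recovery — is
#' unchanged.
#'
#' @param truth a [synthetic_truth()]; `truth$matrix_factors` supplies the
#'   per-lot factors (unit factors if `NULL`).
#' @param n_lots number of blank-matrix lots.
#' @param levels spike concentrations (ug/mL); default the middle three
#'   validation levels of `analyte` in the caftor panel.
#' @param analyte analyte id for the emitted records.
#' @return a `measurements` table with role `"matrix_lot"`.
#' @export
generate_matrix_lot_panel <- function(truth, n_lots = 10, levels = NULL,
                                      analyte = "IVA") {
  stopifnot(inherits(truth, "synthetic_truth"), n_lots >= 1L)
  if (is.null(levels)) {
    qp <- caftor_panel("qc_validation")
    conc <- sort(qp$conc_ug_ml[qp$analyte == analyte])
    levels <- conc[c(2L, 3L, 4L)]
  }
  stopifnot(all(levels > 0))
  mf <- truth$matrix_factors
  if (is.null(mf)) {
    mf <- data.frame(lot = sprintf("lot%02d", seq_len(n_lots)),
                     analyte_factor = 1, is_factor = 1,
                     stringsAsFactors = FALSE)
  } else if (nrow(mf) < n_lots) {
    stop("matrix_factors has fewer rows than n_lots", call. = FALSE)
  }
  mf <- mf[seq_len(n_lots), , drop = FALSE]
  if (!is.null(truth$seed)) set.seed(truth$seed)
  cv <- mean(recycle_levels(truth$s_within_pct,
                            max(length(truth$s_within_pct), 1L),
                            "s_within_pct")) / 100
  grid <- expand.grid(lot = seq_len(n_lots), conc = levels)
  meas <- grid$conc * (1 + rnorm(nrow(grid), 0, cv))
  meas[meas <= 0] <- grid$conc[meas <= 0] * 1e-6
  as_measurements(data.frame(
    analyte = analyte, role = "matrix_lot", day = 1L, replicate = 1L,
    nominal_ug_ml = grid$conc,
    analyte_area = conc_to_ratio(truth, meas) * truth$is_area *
      mf$analyte_factor[grid$lot],
    is_area = truth$is_area * mf$is_factor[grid$lot],
    lot = as.character(mf$lot[grid$lot]), stringsAsFactors = FALSE))
}

#' Generate a toy chromatographic trace
#'
#' A Gaussian peak on a flat baseline with additive white noise, as a
#' fixture for signal-to-noise and limit-of-detection logic. The ground-truth
#' S/N (`peak_height / noise_sd`, `Inf` when noise-free) travels with the
#' trace.
#'
#' @param peak_height peak height above baseline (response units).
#' @param noise_sd SD of the additive baseline noise (>= 0).
#' @param n_points number of sampled points (>= 50).
#' @param seed optional integer seed.
#' @return an object of class `chromatogram`: list with `time` (0..1),
#'   `intensity`, index vectors `peak_window` and `baseline_window`, and
#'   `truth`.
#' @export
generate_chromatogram <- function(peak_height, noise_sd, n_points = 1000,
                                  seed = NULL) {
  stopifnot(peak_height >= 0, noise_sd >= 0, n_points >= 50L)
  if (!is.null(seed)) set.seed(seed)
  time <- seq(0, 1, length.out = n_points)
  signal <- peak_height * exp(-0.5 * ((time - 0.3) / 0.015)^2)
  intensity <- signal + rnorm(n_points, 0, noise_sd)
  structure(
    list(time = time, intensity = intensity,
         peak_window = which(time >= 0.25 & time <= 0.35),
         baseline_window = which(time >= 0.5),
         truth = list(peak_height = peak_height, noise_sd = noise_sd,
                      sn = if (noise_sd == 0) Inf else peak_height / noise_sd)),
    class = "chromatogram"
  )
}
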