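## Per-level summaries (the validation-report block: trueness, repeatability,
## intermediate precision, tolerance bounds, expanded uncertainty) and the
## accuracy profile with LLOQ/ULOQ determination.
##
## All precision quantities are expressed as CV% of the nominal
## concentration, the unit validation reports print.

level_summary_row <- function(nominal, trueness_pct, s_r_pct, s_b_pct,
                              design, config) {
  bias <- trueness_pct - 100
  s_ip <- sqrt(s_r_pct^2 + s_b_pct^2)
  ti <- beta_expectation_interval(bias, s_r_pct, s_b_pct,
                                  tolerance_design(design$p, design$n,
                                                   config$beta_profile))
  mu <- measurement_uncertainty(s_r_pct, s_b_pct,
                                tolerance_design(design$p, design$n,
                                                 config$beta_mu))
  data.frame(
    nominal = nominal, mean_measured = trueness_pct / 100 * nominal,
    trueness_pct = trueness_pct, bias_pct = bias,
    s_r_pct = s_r_pct, s_b_pct = s_b_pct, s_ip_pct = s_ip,
    R = attr(ti, "R"), B2 = attr(ti, "B2"), nu = attr(ti, "nu"),
    tol_low_pct = unname(ti[1]), tol_high_pct = unname(ti[2]),
    mu_expanded_pct = mu)
}

#' Summarize back-calculated QCs per concentration level
#'
#' For each nominal level, computes trueness (mean measured as percent of
#' nominal), repeatability and intermediate-precision CV%, the
#' beta-expectation tolerance bounds (at `config$beta_profile`) and the
#' expanded measurement uncertainty (at `config$beta_mu`) from a balanced
#' day x replicate design. Variance components are estimated on the
#' relative (percent-of-nominal) scale.
#'
#' @param back_calc_qcs data.frame with columns `nominal`, `day` and `conc`
#'   (back-calculated concentration, same units as `nominal`).
#' @param design optional list/`tolerance_design` with `p` and `n`; inferred
#'   from the data when `NULL`.
#' @param config a [validation_config()].
#' @return a data.frame of class `level_summary`, one row per level, sorted
#'   by nominal concentration.
#' @export
summarize_levels <- function(back_calc_qcs, design = NULL,
                             config = validation_config()) {
  stopifnot(all(c("nominal", "day", "conc") %in% names(back_calc_qcs)))
  levels <- sort(unique(back_calc_qcs$nominal))
  rows <- lapply(levels, function(nom) {
    sub <- back_calc_qcs[back_calc_qcs$nominal == nom, , drop = FALSE]
    rel <- sub$conc / nom * 100
    vc <- variance_components(rel, sub$day)
    des <- if (is.null(design)) list(p = vc$p, n = round(vc$n)) else design
    level_summary_row(nom, vc$grand_mean, vc$s_within, vc$s_between,
                      des, config)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("level_summary", "data.frame")
  out
}

#' Reconstruct level summaries from printed validation statistics
#'
#' Builds the same per-level block as [summarize_levels()] when only the
#' reported summary statistics are available (trueness %, repeatability CV%,
#' intermediate-precision CV%), as printed in validation reports. The
#' between-day component is recovered as
#' `s_b^2 = max(0, s_IP^2 - s_r^2)`.
#'
#' @param nominal nominal concentrations (ug/mL).
#' @param trueness_pct mean measured concentration, percent of nominal.
#' @param s_r_pct repeatability CV%.
#' @param s_ip_pct intermediate-precision CV%.
#' @param design list/`tolerance_design` with `p` and `n` of the validation
#'   design.
#' @param config a [validation_config()].
#' @return a `level_summary` data.frame.
#' @examples
#' design <- list(p = 3, n = 3)
#' level_summary_from_stats(c(0.15, 0.3), c(89.8, 91.0), c(4.0, 4.9),
#'                          c(10.9, 6.4), design)
#' @export
level_summary_from_stats <- function(nominal, trueness_pct, s_r_pct,
                                     s_ip_pct, design,
                                     config = validation_config()) {
  stopifnot(length(nominal) == length(trueness_pct),
            length(nominal) == length(s_r_pct),
            length(nominal) == length(s_ip_pct),
            all(s_r_pct >= 0), all(s_ip_pct >= 0))
  rows <- lapply(seq_along(nominal), function(i) {
    s_b <- sqrt(max(0, s_ip_pct[i]^2 - s_r_pct[i]^2))
    level_summary_row(nominal[i], trueness_pct[i], s_r_pct[i], s_b,
                      design, config)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$nominal), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("level_summary", "data.frame")
  out
}

#' Assemble an accuracy profile
#'
#' Orders the level summaries, attaches the acceptance limits and determines
#' LLOQ/ULOQ. The profile is the total-error picture of the method: per
#' level, the bias and the beta-expectation tolerance bounds against the
#' +/-lambda acceptance corridor.
#'
#' @param level_summaries a `level_summary` data.frame (>= 2 distinct
#'   levels).
#' @param config a [validation_config()]; `acceptance_profile_pct` is the
#'   corridor half-width lambda.
#' @param analyte_id optional analyte label carried in the profile.
#' @return object of class `accuracy_profile`: list with `analyte_id`,
#'   `levels`, `beta`, `lambda_pct`, `lloq`, `uloq`.
#' @export
build_accuracy_profile <- function(level_summaries,
                                   config = validation_config(),
                                   analyte_id = NA_character_) {
  stopifnot(is.data.frame(level_summaries), nrow(level_summaries) >= 1L)
  if (nrow(level_summaries) < 2L) {
    stop("an accuracy profile needs at least two concentration levels",
         call. = FALSE)
  }
  if (anyDuplicated(level_summaries$nominal)) {
    stop("duplicate nominal levels in the profile", call. = FALSE)
  }
  levels <- level_summaries[order(level_summaries$nominal), , drop = FALSE]
  rownames(levels) <- NULL
  profile <- structure(
    list(analyte_id = analyte_id, levels = levels,
         beta = config$beta_profile,
         lambda_pct = config$acceptance_profile_pct,
         lloq = NA_real_, uloq = NA_real_),
    class = "accuracy_profile")
  profile$lloq <- determine_lloq(profile)
  if (!is.na(profile$lloq)) profile$uloq <- max(levels$nominal)
  profile
}

#' Lower limit of quantification from an accuracy profile
#'
#' The smallest validated level whose tolerance interval lies entirely
#' within the +/-lambda acceptance limits, provided every higher level also
#' passes; failing levels below it are excluded from the reported range. No
#' interpolation between levels is performed: the LLOQ is always one of the
#' validated concentrations. When no level qualifies the result is `NA`
#' (an explicit no-valid-LLOQ sentinel, not an error).
#'
#' @param profile an `accuracy_profile`.
#' @return LLOQ in ug/mL, or `NA_real_`.
#' @export
determine_lloq <- function(profile) {
  stopifnot(inherits(profile, "accuracy_profile"))
  lv <- profile$levels
  if (!nrow(lv)) stop("empty accuracy profile", call. = FALSE)
  lambda <- profile$lambda_pct
  passes <- lv$tol_low_pct >= -lambda & lv$tol_high_pct <= lambda
  ## longest all-passing tail of the (ascending) level sequence
  tail_ok <- rev(cumprod(rev(passes))) == 1
  if (!any(tail_ok)) return(NA_real_)
  lv$nominal[which(tail_ok)[1L]]
}

#' Plot-ready series of an accuracy profile
#'
#' @param profile an `accuracy_profile`.
#' @return data.frame with `level`, `bias_pct`, `tol_low_pct`,
#'   `tol_high_pct`, `lower_limit_pct`, `upper_limit_pct`, `passes` —
#'   consumable by any plotting layer.
#' @export
profile_series <- function(profile) {
  stopifnot(inherits(profile, "accuracy_profile"))
  lv <- profile$levels
  data.frame(level = lv$nominal, bias_pct = lv$bias_pct,
             tol_low_pct = lv$tol_low_pct, tol_high_pct = lv$tol_high_pct,
             lower_limit_pct = -profile$lambda_pct,
             upper_limit_pct = profile$lambda_pct,
             passes = lv$tol_low_pct >= -profile$lambda_pct &
               lv$tol_high_pct <= profile$lambda_pct)
}

#' @export
print.accuracy_profile <- function(x, ...) {
  cat(sprintf("Accuracy profile%s (beta = %.2f, limits +/-%g%%)\n",
              if (is.na(x$analyte_id)) "" else paste0(" - ", x$analyte_id),
              x$beta, x$lambda_pct))
  show <- x$levels[c("nominal", "trueness_pct", "s_r_pct", "s_ip_pct",
                     "tol_low_pct", "tol_high_pct", "mu_expanded_pct")]
  print.data.frame(format(show, digits = 3), row.names = FALSE)
  if (is.na(x$lloq)) {
    cat("no valid LLOQ: no level passes the acceptance limits\n")
  } else {
    cat(sprintf("LLOQ = %g ug/mL, ULOQ = %g ug/mL\n", x$lloq, x$uloq))
  }
  invisible(x)
}
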