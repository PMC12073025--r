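## Assembly and serialization of the validation report: per analyte, the
## calibration diagnostics, the per-level trueness/precision block, the
## accuracy-profile bounds with LLOQ/ULOQ, and the pass/fail flag of every
## executed check. The structured (JSON) form is the machine-readable record;
## the text form rounds to one decimal, as validation reports print.

#' Assemble a validation report
#'
#' @param analytes named list (one entry per analyte), each a list with any
#'   of: `calibration` (a `calibration_fit` or coefficient list), `levels`
#'   (a `level_summary` data.frame), `profile` (an `accuracy_profile`),
#'   `checks` (list of `check_result`s).
#' @param config the [validation_config()] used.
#' @return object of class `validation_report`, with a global `summary`
#'   (trueness range, maximal repeatability and intermediate precision over
#'   all analytes and levels) and an `overall_passed` flag (all profiles
#'   have a valid LLOQ and all executed checks passed).
#' @export
validation_report <- function(analytes, config = validation_config()) {
  stopifnot(is.list(analytes), length(analytes) >= 1L,
            !is.null(names(analytes)))
  has_stage <- vapply(analytes, function(a) {
    any(c("calibration", "levels", "profile", "checks") %in% names(a))
  }, logical(1))
  if (!any(has_stage)) {
    stop("no stage outputs present: nothing to report", call. = FALSE)
  }
  blocks <- lapply(analytes, function(a) a$levels)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  summary <- if (length(blocks)) {
    all_levels <- do.call(rbind, blocks)
    list(trueness_min_pct = min(all_levels$trueness_pct),
         trueness_max_pct = max(all_levels$trueness_pct),
         repeatability_max_pct = max(all_levels$s_r_pct),
         intermediate_precision_max_pct = max(all_levels$s_ip_pct),
         n_levels = nrow(all_levels))
  } else NULL

  flags <- unlist(lapply(analytes, function(a) {
    ok <- logical(0)
    if (!is.null(a$profile)) ok <- c(ok, !is.na(a$profile$lloq))
    for (ch in a$checks) {
      if (inherits(ch, "check_result")) ok <- c(ok, ch$passed)
      else if (is.list(ch)) {
        ok <- c(ok, vapply(ch, function(x) isTRUE(x$passed), logical(1)))
      }
    }
    ok
  }))
  structure(list(config = config, analytes = analytes, summary = summary,
                 overall_passed = length(flags) > 0 && all(flags)),
            class = "validation_report")
}

#' Global ranges of a validation report
#'
#' The headline numbers of a validation campaign: minimal and maximal
#' trueness, maximal repeatability and maximal intermediate precision over
#' every analyte and level.
#'
#' @param x a `validation_report`, or a data.frame of level summaries with
#'   columns `trueness_pct`, and either `s_r_pct`/`s_ip_pct` or
#'   `repeatability_pct`/`intermediate_precision_pct`.
#' @return named numeric: `trueness_min`, `trueness_max`,
#'   `repeatability_max`, `intermediate_precision_max`.
#' @export
report_ranges <- function(x) {
  if (inherits(x, "validation_report")) {
    s <- x$summary
    if (is.null(s)) stop("report has no level summaries", call. = FALSE)
    return(c(trueness_min = s$trueness_min_pct,
             trueness_max = s$trueness_max_pct,
             repeatability_max = s$repeatability_max_pct,
             intermediate_precision_max = s$intermediate_precision_max_pct))
  }
  stopifnot(is.data.frame(x))
  s_r <- if ("s_r_pct" %in% names(x)) x$s_r_pct else x$repeatability_pct
  s_ip <- if ("s_ip_pct" %in% names(x)) x$s_ip_pct else
    x$intermediate_precision_pct
  c(trueness_min = min(x$trueness_pct), trueness_max = max(x$trueness_pct),
    repeatability_max = max(s_r), intermediate_precision_max = max(s_ip))
}

#' Accuracy profiles from a printed summary block
#'
#' Rebuilds per-analyte accuracy profiles from a table of reported summary
#' statistics (the shape validation reports print: one row per analyte and
#' level with trueness, repeatability and intermediate precision), via
#' [level_summary_from_stats()].
#'
#' @param summary_block data.frame with columns `analyte`, `conc_ug_ml`,
#'   `trueness_pct`, `repeatability_pct`, `intermediate_precision_pct`
#'   (the shape of [caftor_validation_summary()]).
#' @param design list with `p` and `n` of the validation design.
#' @param config a [validation_config()].
#' @return named list of `accuracy_profile`s.
#' @export
profiles_from_summary <- function(summary_block, design = list(p = 3, n = 3),
                                  config = validation_config()) {
  needed <- c("analyte", "conc_ug_ml", "trueness_pct", "repeatability_pct",
              "intermediate_precision_pct")
  stopifnot(all(needed %in% names(summary_block)))
  out <- list()
  for (a in unique(summary_block$analyte)) {
    sub <- summary_block[summary_block$analyte == a, , drop = FALSE]
    ls <- level_summary_from_stats(sub$conc_ug_ml, sub$trueness_pct,
                                   sub$repeatability_pct,
                                   sub$intermediate_precision_pct,
                                   design, config)
    out[[a]] <- build_accuracy_profile(ls, config, analyte_id = a)
  }
  out
}

## ---- serialization -------------------------------------------------------

as_plain <- function(x) {
  if (inherits(x, "calibration_fit")) {
    return(list(family = x$spec$family, transform = x$spec$transform,
                weighting = x$spec$weighting,
                coeffs = as.list(x$coeffs), r_squared = x$r_squared,
                linearity_slope = x$linearity_slope,
                range_ug_ml = x$range,
                back_calc = x$back_calc))
  }
  if (inherits(x, "accuracy_profile")) {
    return(list(analyte = x$analyte_id, beta = x$beta,
                lambda_pct = x$lambda_pct,
                lloq_ug_ml = x$lloq, uloq_ug_ml = x$uloq,
                series = profile_series(x)))
  }
  if (inherits(x, "check_result")) {
    return(list(check = x$check_name, statistic_pct = x$statistic_pct,
                threshold_pct = x$threshold_pct,
                comparison = x$comparison, passed = x$passed,
                detail = x$detail))
  }
  if (inherits(x, "validation_config")) return(unclass(x))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, as_plain))
  x
}

#' Write a validation report to disk
#'
#' `format = "structured"` writes JSON (every number of the text form is
#' traceable to a field here); `format = "text"` writes a human-readable
#' summary with values rounded to one decimal.
#'
#' @param results a `validation_report`.
#' @param path destination file.
#' @param format `"structured"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("structured", "text")) {
  stopifnot(inherits(results, "validation_report"))
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("unwritable path: directory does not exist: ", dir, call. = FALSE)
  }
  if (format == "structured") {
    payload <- list(config = as_plain(results$config),
                    analytes = as_plain(results$analytes),
                    summary = results$summary,
                    overall_passed = results$overall_passed)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, na = "null", force = TRUE)
  } else {
    lines <- format_report_text(results)
    writeLines(lines, path)
  }
  invisible(path)
}

format_report_text <- function(x) {
  f1 <- function(v) formatC(v, format = "f", digits = 1)
  lines <- c("Assay validation report",
             strrep("=", 60))
  for (a in names(x$analytes)) {
    blk <- x$analytes[[a]]
    lines <- c(lines, "", paste0("Analyte: ", a), strrep("-", 40))
    if (!is.null(blk$calibration)) {
      cal <- as_plain(blk$calibration)
      lines <- c(lines, sprintf(
        "  calibration: %s (%s), R^2 = %s, slope = %s",
        cal$family, cal$transform, formatC(cal$r_squared, digits = 4,
                                           format = "f"),
        formatC(cal$linearity_slope, digits = 3, format = "f")))
    }
    if (!is.null(blk$levels)) {
      lines <- c(lines,
                 "  level    trueness%  repeat%  interm.prec%  tol.low%  tol.high%  MU%")
      for (i in seq_len(nrow(blk$levels))) {
        lv <- blk$levels[i, ]
        lines <- c(lines, sprintf(
          "  %-8s %-10s %-8s %-13s %-9s %-10s %s",
          format(lv$nominal), f1(lv$trueness_pct), f1(lv$s_r_pct),
          f1(lv$s_ip_pct), f1(lv$tol_low_pct), f1(lv$tol_high_pct),
          f1(lv$mu_expanded_pct)))
      }
    }
    if (!is.null(blk$profile)) {
      lines <- c(lines, if (is.na(blk$profile$lloq)) {
        "  LLOQ: none (no level passes the acceptance limits)"
      } else {
        sprintf("  LLOQ = %g ug/mL, ULOQ = %g ug/mL (beta = %.2f, +/-%g%%)",
                blk$profile$lloq, blk$profile$uloq, blk$profile$beta,
                blk$profile$lambda_pct)
      })
    }
    for (ch in blk$checks) {
      items <- if (inherits(ch, "check_result")) list(ch) else ch
      for (it in items) {
        lines <- c(lines, sprintf("  check %-28s %s (%s%%)",
                                  it$check_name,
                                  if (it$passed) "PASS" else "FAIL",
                                  f1(it$statistic_pct)))
      }
    }
  }
  if (!is.null(x$summary)) {
    s <- x$summary
    lines <- c(lines, "", strrep("=", 60), sprintf(
      "Global: trueness %s-%s%%, repeatability <= %s%%, intermediate precision <= %s%%",
      f1(s$trueness_min_pct), f1(s$trueness_max_pct),
      f1(s$repeatability_max_pct), f1(s$intermediate_precision_max_pct)))
  }
  c(lines, sprintf("Overall: %s",
                   if (x$overall_passed) "PASS" else "FAIL"))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}
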