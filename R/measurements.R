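## Injection-level data model shared by every stage.

MEASUREMENT_ROLES <- c("calibrator", "qc", "blank", "double_blank",
                       "stability", "matrix_lot", "dilution_qc",
                       "patient", "ilc")

## roles whose nominal concentration must be a positive number
NOMINAL_REQUIRED_ROLES <- c("calibrator", "qc", "stability", "matrix_lot",
                            "dilution_qc")

MEASUREMENT_COLUMNS <- c("analyte", "role", "day", "replicate",
                         "nominal_ug_ml", "analyte_area", "is_area",
                         "lot", "matrix", "temperature", "time_h", "cycle",
                         "dilution")

#' Construct a measurements table
#'
#' Validates a data.frame of per-injection records and stamps it with the
#' `measurements` class. Required columns: `analyte`, `role`, `day`,
#' `replicate`; optional: `nominal_ug_ml`, `analyte_area`, `is_area`, `lot`,
#' `matrix`, `temperature`, `time_h`, `cycle`, `dilution`. Concentrations are
#' ug/mL throughout.
#'
#' Enforced invariants: known roles; `analyte_area >= 0`; `is_area > 0` where
#' present (>= 0 is tolerated for blank roles, whose channel signal may be
#' genuinely zero); positive nominal concentration for calibrator, QC,
#' stability, matrix-lot and dilution-QC records; and uniqueness of
#' `(day, replicate)` within `(analyte, role, nominal, lot, condition)`.
#' Violations are reported with their row numbers.
#'
#' @param df data.frame of injection records.
#' @return the validated data.frame, classed `measurements`.
#' @export
as_measurements <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("analyte", "role", "day", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(MEASUREMENT_COLUMNS, names(df))) df[[col]] <- NA
  extras <- setdiff(names(df), MEASUREMENT_COLUMNS)  # e.g. conc_back_ug_ml
  df <- df[c(MEASUREMENT_COLUMNS, extras)]
  df$analyte <- as.character(df$analyte)
  df$role <- as.character(df$role)
  for (col in c("day", "replicate", "cycle")) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  for (col in c("nominal_ug_ml", "analyte_area", "is_area", "time_h",
                "dilution")) {
    df[[col]] <- if (is.numeric(df[[col]])) as.numeric(df[[col]]) else
      suppressWarnings(as.numeric(as.character(df[[col]])))
  }

  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad)) {
      problems <<- c(problems, sprintf("%s (row %s)", msg,
                                       paste(which(bad), collapse = ", ")))
    }
  }
  flag(is.na(df$analyte) | !nzchar(df$analyte), "empty analyte id")
  flag(!(df$role %in% MEASUREMENT_ROLES),
       sprintf("unknown role (expected one of %s)",
               paste(MEASUREMENT_ROLES, collapse = "/")))
  flag(is.na(df$day) | df$day < 1L, "day index must be a positive integer")
  flag(is.na(df$replicate) | df$replicate < 1L,
       "replicate index must be a positive integer")
  flag(!is.na(df$analyte_area) & df$analyte_area < 0,
       "analyte_area must be nonnegative")
  is_blankish <- df$role %in% c("blank", "double_blank")
  flag(!is.na(df$is_area) & ifelse(is_blankish, df$is_area < 0,
                                   df$is_area <= 0),
       "is_area must be positive where present")
  needs_nominal <- df$role %in% NOMINAL_REQUIRED_ROLES
  flag(needs_nominal & (is.na(df$nominal_ug_ml) | df$nominal_ug_ml <= 0),
       "nominal_ug_ml must be positive for this role")
  flag(!is.na(df$time_h) & df$time_h < 0, "time_h must be nonnegative")

  key <- paste(df$analyte, df$role, df$nominal_ug_ml, df$lot, df$matrix,
               df$temperature, df$time_h, df$cycle, df$day, df$replicate,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first_dup <- which(dup)[1L]
    problems <- c(problems, sprintf(
      "duplicated (day, replicate) key: analyte=%s role=%s nominal=%s day=%d replicate=%d (row %s)",
      df$analyte[first_dup], df$role[first_dup], df$nominal_ug_ml[first_dup],
      df$day[first_dup], df$replicate[first_dup],
      paste(which(dup), collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid measurement record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  class(df) <- c("measurements", "data.frame")
  df
}

#' Read injection records from a delimited text file
#'
#' Accepts comma- or tab-separated files with a header row. Column names can
#' be remapped through `schema` (a named character vector,
#' `canonical = file_column`). If a `unit` column is present, rows in ng/mL
#' are converted to the internal ug/mL scale (x 1e-3).
#'
#' @param path file path.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return a `measurements` table, in file order.
#' @export
read_measurements <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
  if (!is.null(schema)) {
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent)) {
      stop("schema refers to missing column(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    for (canonical in names(schema)) {
      names(raw)[names(raw) == schema[[canonical]]] <- canonical
    }
  }
  required <- c("analyte", "role", "day", "replicate")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("analyte_area", "is_area", "nominal_ug_ml")) {
    if (col %in% names(raw) && !is.numeric(raw[[col]])) {
      coerced <- suppressWarnings(as.numeric(as.character(raw[[col]])))
      bad <- !is.na(raw[[col]]) & is.na(coerced)
      if (any(bad)) {
        stop(sprintf("non-numeric %s (row %s)", col,
                     paste(which(bad), collapse = ", ")), call. = FALSE)
      }
      raw[[col]] <- coerced
    }
  }
  if ("unit" %in% names(raw)) {
    unit <- tolower(ifelse(is.na(raw$unit), "ug_ml", raw$unit))
    known <- unit %in% c("ug_ml", "ng_ml")
    if (!all(known)) {
      stop("unknown unit value(s): ",
           paste(unique(raw$unit[!known]), collapse = ", "), call. = FALSE)
    }
    if ("nominal_ug_ml" %in% names(raw)) {
      raw$nominal_ug_ml <- raw$nominal_ug_ml * ifelse(unit == "ng_ml", 1e-3, 1)
    }
    raw$unit <- NULL
  }
  as_measurements(raw)
}

#' Write a measurements table to delimited text
#'
#' Writes the canonical column set as CSV with full numeric precision, so
#' that [read_measurements()] round-trips losslessly.
#'
#' @param x a `measurements` table (or coercible data.frame).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  x <- as_measurements(x)
  out <- as.data.frame(x)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           formatC(out[[col]], digits = 17, format = "g"))
    }
  }
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Summarize the measurement design of a dataset
#'
#' Per-analyte counts of calibrator levels, QC levels, days and replicates,
#' with incomplete day x replicate cells flagged (not failed): a run sheet
#' sanity check before any statistics are computed. Counts are invariant to
#' row order.
#'
#' @param measurements a `measurements` table.
#' @param config a [validation_config()] (reserved for future per-role
#'   expectations; unused fields are ignored).
#' @return an object of class `design_summary`: a per-analyte data.frame with
#'   attribute `incomplete` listing missing `(analyte, nominal, day)` cells.
#' @export
validate_dataset <- function(measurements, config = validation_config()) {
  m <- as_measurements(measurements)
  if (nrow(m) == 0L) stop("empty measurement collection", call. = FALSE)
  analytes <- sort(unique(m$analyte))
  rows <- lapply(analytes, function(a) {
    ma <- m[m$analyte == a, , drop = FALSE]
    cal <- ma[ma$role == "calibrator", , drop = FALSE]
    qc <- ma[ma$role == "qc", , drop = FALSE]
    data.frame(
      analyte = a,
      n_records = nrow(ma),
      cal_levels = length(unique(cal$nominal_ug_ml)),
      cal_replicates = if (nrow(cal)) max(table(cal$nominal_ug_ml)) else 0L,
      qc_levels = length(unique(qc$nominal_ug_ml)),
      days = length(unique(qc$day)),
      replicates = if (nrow(qc)) {
        max(table(paste(qc$nominal_ug_ml, qc$day)))
      } else 0L,
      stringsAsFactors = FALSE
    )
  })
  summary_df <- do.call(rbind, rows)

  qc <- m[m$role == "qc", , drop = FALSE]
  incomplete <- NULL
  if (nrow(qc)) {
    all_days <- sort(unique(qc$day))
    cells <- unique(qc[c("analyte", "nominal_ug_ml")])
    miss <- lapply(seq_len(nrow(cells)), function(i) {
      present <- qc$day[qc$analyte == cells$analyte[i] &
                          qc$nominal_ug_ml == cells$nominal_ug_ml[i]]
      gone <- setdiff(all_days, present)
      if (!length(gone)) return(NULL)
      data.frame(analyte = cells$analyte[i],
                 nominal_ug_ml = cells$nominal_ug_ml[i],
                 missing_day = gone, stringsAsFactors = FALSE)
    })
    miss <- miss[!vapply(miss, is.null, logical(1))]
    if (length(miss)) incomplete <- do.call(rbind, miss)
  }
  structure(summary_df, incomplete = incomplete,
            class = c("design_summary", "data.frame"))
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Measurement design summary\n")
  print.data.frame(x, row.names = FALSE)
  inc <- attr(x, "incomplete")
  if (!is.null(inc) && nrow(inc)) {
    cat(sprintf("%d incomplete QC cell(s) flagged:\n", nrow(inc)))
    print.data.frame(inc, row.names = FALSE)
  } else {
    cat("design complete: no missing QC cells\n")
  }
  invisible(x)
}

## analyte/IS response ratio; falls back to the raw analyte area (with a
## warning) when no internal standard was acquired, except for blank-type
## injections where IS-free acquisition is by design.
response_ratio <- function(m, warn = TRUE) {
  ratio <- m$analyte_area / m$is_area
  no_is <- is.na(m$is_area)
  if (any(no_is)) {
    blankish <- m$role %in% c("blank", "double_blank")
    if (warn && any(no_is & !blankish)) {
      warning(sprintf("%d record(s) without internal standard: using raw analyte area",
                      sum(no_is & !blankish)), call. = FALSE)
    }
    ratio[no_is] <- m$analyte_area[no_is]
  }
  ratio
}
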