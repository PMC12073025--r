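test_that("a seed alone drives a full seven-analyte validation run", {
  rep <- run_validation(seed = 2024)
  expect_s3_class(rep, "validation_report")
  expect_length(rep$analytes, 7)
  for (a in names(rep$analytes)) {
    blk <- rep$analytes[[a]]
    expect_equal(nrow(blk$levels), 5)
    expect_false(is.na(blk$profile$lloq))
    expect_false(is.na(blk$profile$uloq))
  }
  expect_true(rep$overall_passed)
})

test_that("the same seed and config give an identical structured report", {
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(run_validation(seed = 7), p1)
  write_report(run_validation(seed = 7), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a dataset without QCs yields a calibration-only report", {
  m <- generate_validation_dataset(default_synthetic_truth(31))
  m <- m[m$role == "calibrator" & m$analyte == "IVA", ]
  expect_message(rep <- run_validation(m, verbose = TRUE), "no QCs")
  blk <- rep$analytes$IVA
  expect_false(is.null(blk$calibration))
  expect_null(blk$profile)
  expect_null(blk$levels)
})

test_that("a corrupted dataset with huge bias fails the campaign", {
  truth <- synthetic_truth(calib_coeffs = c(0, 1, -0.04),
                           bias_pct = 60, s_within_pct = 3,
                           s_between_pct = 2, seed = 5)
  m <- generate_validation_dataset(truth)
  rep <- run_validation(m)
  expect_false(rep$overall_passed)
  # fitted with the correct model family, no level can absorb a +60% bias
  rep2 <- run_validation(m, candidates = list(
    quad = calibration_spec("quadratic", "log_log"),
    lin = calibration_spec("linear", "log_log")))
  expect_false(rep2$overall_passed)
  lloqs <- vapply(rep2$analytes, function(b) b$profile$lloq, numeric(1))
  expect_true(all(is.na(lloqs)))
})

test_that("patient quantification round-trips ratios and applies range flags", {
  truth <- synthetic_truth(calib_coeffs = c(0, 1, -0.04))
  panel <- caftor_panel()
  m <- generate_validation_dataset(truth,
                                   panel = panel[panel$analyte == "ELX", ])
  fit <- fit_calibration(m[m$role == "calibrator", ])
  prof <- build_accuracy_profile(summarize_levels(
    data.frame(nominal = m$nominal_ug_ml[m$role == "qc"],
               day = m$day[m$role == "qc"],
               conc = back_calculate(fit, with(m[m$role == "qc", ],
                                               analyte_area / is_area)))),
    analyte_id = "ELX")

  qc_levels <- panel[panel$analyte == "ELX" & panel$role == "qc_routine",
                     "conc_ug_ml"]
  batch_qc <- do.call(rbind, lapply(seq_along(qc_levels), function(i) {
    meas_row(analyte = "ELX", role = "qc", replicate = i,
             nominal_ug_ml = qc_levels[i],
             analyte_area = predict(fit, qc_levels[i]) * 1e5, is_area = 1e5)
  }))

  patient_at <- function(conc, dilution = NA) {
    meas_row(analyte = "ELX", role = "patient",
             analyte_area = predict(fit, conc) * 1e5, is_area = 1e5,
             dilution = dilution)
  }
  # a patient at exactly CAL3's response back-calculates to CAL3's nominal
  cal3 <- sort(unique(m$nominal_ug_ml[m$role == "calibrator"]))[3]
  res <- quantify_patients(patient_at(cal3), fit, batch_qc, prof)
  expect_equal(res$conc_ug_ml, cal3, tolerance = 1e-9)
  expect_true(res$qc_batch_passed)
  expect_false(res$below_lloq || res$above_uloq || res$diluted)

  # the triple-therapy example concentration is recovered from its ratio
  res2 <- quantify_patients(patient_at(6.92), fit, batch_qc, prof)
  expect_equal(res2$conc_ug_ml, 6.92, tolerance = 1e-9)

  # below-LLOQ response: flag raised, no numeric value reported
  low <- quantify_patients(patient_at(0.02), fit, batch_qc, prof)
  expect_true(low$below_lloq)
  expect_false(low$above_uloq)
  expect_true(is.na(low$conc_ug_ml))

  # above-ULOQ response is flagged; a declared dilution scales back in range
  high <- quantify_patients(patient_at(16), fit, batch_qc, prof)
  expect_true(high$above_uloq)
  diluted <- quantify_patients(patient_at(1.5, dilution = 10), fit,
                               batch_qc, prof)
  expect_true(diluted$diluted)
  expect_equal(diluted$conc_ug_ml, 15, tolerance = 1e-9)
})

test_that("a failed batch QC flags every result and warns loudly", {
  truth <- synthetic_truth()
  panel <- caftor_panel()
  m <- generate_validation_dataset(truth,
                                   panel = panel[panel$analyte == "IVA", ])
  fit <- fit_calibration(m[m$role == "calibrator", ],
                         calibration_spec("linear", "log_log"))
  prof <- build_accuracy_profile(summarize_levels(
    data.frame(nominal = m$nominal_ug_ml[m$role == "qc"],
               day = m$day[m$role == "qc"],
               conc = m$nominal_ug_ml[m$role == "qc"])), analyte_id = "IVA")
  qc_levels <- c(0.15, 0.75, 3.75)
  bad_qc <- do.call(rbind, lapply(seq_along(qc_levels), function(i) {
    meas_row(role = "qc", replicate = i, nominal_ug_ml = qc_levels[i],
             analyte_area = predict(fit, qc_levels[i] * 1.3) * 1e5,
             is_area = 1e5)  # +30% deviation at every level
  }))
  patient <- meas_row(role = "patient", analyte_area = predict(fit, 1) * 1e5,
                      is_area = 1e5)
  expect_warning(res <- quantify_patients(patient, fit, bad_qc, prof),
                 "batch QC FAILED")
  expect_false(res$qc_batch_passed)
  expect_equal(res$conc_ug_ml, 1, tolerance = 1e-9)
})
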