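test_that("noise-free identity and quadratic curves are recovered exactly", {
  fit <- fit_calibration(exact_calibrators(c(0, 1, 0)),
                         calibration_spec("quadratic", "log_log"))
  expect_equal(unname(fit$coeffs), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$linearity_slope, 1, tolerance = 1e-9)

  truth <- c(0.3, 0.9, -0.05)
  fit2 <- fit_calibration(exact_calibrators(truth),
                          calibration_spec("quadratic", "log_log"))
  expect_equal(unname(fit2$coeffs), truth, tolerance = 1e-9)
  expect_true(all(abs(fit2$back_calc$deviation_pct) < 1e-7))
})

test_that("inverse prediction round-trips and matches the grid-search oracle", {
  fit <- fit_calibration(exact_calibrators(c(0.3, 0.9, -0.05)),
                         calibration_spec("quadratic", "log_log"))
  concs <- exp(seq(log(0.05), log(5), length.out = 11))
  expect_equal(back_calculate(fit, predict(fit, concs)), concs,
               tolerance = 1e-9)

  ratio <- predict(fit, 0.2)  # a mid-range calibrator
  expect_equal(back_calculate(fit, ratio), grid_invert(fit, ratio),
               tolerance = 1e-6)
})

test_that("inversion agrees with dense grid search across random fits", {
  set.seed(404)
  for (i in 1:100) {
    coeffs <- c(runif(1, -1, 1), runif(1, 0.8, 1.2), runif(1, -0.05, 0.05))
    fit <- fit_calibration(exact_calibrators(coeffs),
                           calibration_spec("quadratic", "log_log"))
    conc <- exp(runif(1, log(0.05), log(5)))
    ratio <- predict(fit, conc)
    expect_equal(back_calculate(fit, ratio), grid_invert(fit, ratio),
                 tolerance = 1e-6)
  }
})

test_that("degenerate designs, nonpositive ratios and bad roots error", {
  few <- exact_calibrators(c(0, 1, 0), concs = c(0.1, 1, 10))
  expect_error(fit_calibration(few, calibration_spec("quadratic")),
               ">= 4 distinct")
  neg <- exact_calibrators(c(0, 1, 0))
  neg$analyte_area[1] <- 0
  expect_error(fit_calibration(neg, calibration_spec("linear", "log_log")),
               "nonpositive response ratio")

  fit <- fit_calibration(exact_calibrators(c(0, 1, 0)),
                         calibration_spec("linear", "log_log"))
  expect_error(back_calculate(fit, predict(fit, 100)), "outside")
  expect_error(back_calculate(fit, -1), "positive")
})

test_that("r-squared is invariant to a common rescaling of all areas", {
  set.seed(7)
  m <- generate_validation_dataset(default_synthetic_truth(7))
  cal <- m[m$analyte == "TEZ" & m$role == "calibrator", ]
  f1 <- fit_calibration(cal, calibration_spec("quadratic", "log_log"))
  cal2 <- cal
  cal2$analyte_area <- cal2$analyte_area * 37.5
  cal2$is_area <- cal2$is_area * 37.5
  f2 <- fit_calibration(cal2, calibration_spec("quadratic", "log_log"))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_equal(f1$coeffs, f2$coeffs, tolerance = 1e-9)
})

test_that("noisy calibrators at panel levels keep R^2 > 0.99 and slope near 1", {
  m <- generate_validation_dataset(default_synthetic_truth(12345))
  for (a in unique(m$analyte)) {
    fit <- fit_calibration(m[m$analyte == a & m$role == "calibrator", ],
                           calibration_spec("quadratic", "log_log"))
    expect_gt(fit$r_squared, 0.99)
    expect_true(fit$linearity_slope > 0.94 && fit$linearity_slope < 1.04)
  }
})

test_that("model selection breaks exact ties by parsimony", {
  cal <- exact_calibrators(c(0, 1, 0))
  qc <- generate_validation_dataset(
    synthetic_truth(calib_coeffs = c(0, 1, 0), seed = 1),
    panel = caftor_panel()[caftor_panel()$analyte == "IVA", ])
  qc <- qc[qc$role == "qc", ]
  sel <- select_calibration_model(
    cal, qc, list(quad = calibration_spec("quadratic", "log_log"),
                  lin = calibration_spec("linear", "log_log")))
  # noise-free linear truth: identical zero-width profiles, linear wins
  expect_equal(sel$chosen, "lin")
  expect_equal(sel$ranking$mean_envelope_pct[1],
               sel$ranking$mean_envelope_pct[2], tolerance = 1e-9)
})

test_that("saturating curvature favors the quadratic log-log model", {
  set.seed(99)
  truth <- synthetic_truth(calib_coeffs = c(0, 1, -0.04),
                           s_within_pct = 3, s_between_pct = 2)
  panel <- caftor_panel()[caftor_panel()$analyte == "IVA", ]
  wins <- 0L
  for (i in 1:25) {
    m <- generate_validation_dataset(truth, panel = panel)
    sel <- select_calibration_model(
      m[m$role == "calibrator", ], m[m$role == "qc", ],
      list(quad = calibration_spec("quadratic", "log_log"),
           lin = calibration_spec("linear", "log_log")))
    wins <- wins + (sel$chosen == "quad")
  }
  expect_gt(wins, 20)
})

test_that("the shipped candidate list selects quadratic log-log on the default fixture", {
  m <- generate_validation_dataset(default_synthetic_truth())
  cal <- m[m$analyte == "ELX" & m$role == "calibrator", ]
  qc <- m[m$analyte == "ELX" & m$role == "qc", ]
  sel <- select_calibration_model(cal, qc)
  expect_true("quadratic_log_log" %in% names(default_candidates()))
  expect_equal(sel$chosen, "quadratic_log_log")
})

test_that("all-candidate failure aggregates the per-candidate causes", {
  few <- exact_calibrators(c(0, 1, 0), concs = c(0.1, 1))
  qc <- meas_row(nominal_ug_ml = 0.5, analyte_area = 50, is_area = 100)
  expect_error(
    select_calibration_model(few, qc,
                             list(a = calibration_spec("quadratic"),
                                  b = calibration_spec("linear"))),
    "all candidate models failed")
})
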