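blank_row <- function(analyte_area, is_area = 0, lot = NA) {
  meas_row(role = "blank", analyte_area = analyte_area, is_area = is_area,
           lot = lot)
}

test_that("selectivity honors the strict < 20% / < 5% limits", {
  cal1_area <- 1000; is_ref <- 5000
  clean <- rbind(blank_row(0, 0, "L1"), blank_row(0, 0, "L2"))
  res <- selectivity_check(clean, cal1_area, is_ref)
  expect_true(res$passed)
  expect_equal(res$statistic_pct, 0)

  # 19% of CAL1 passes (strictly below), 20% exactly fails
  expect_true(selectivity_check(blank_row(190), cal1_area, is_ref)$passed)
  expect_false(selectivity_check(blank_row(200), cal1_area, is_ref)$passed)

  # IS-channel interference at 6% fails even with a clean analyte channel
  expect_false(selectivity_check(blank_row(0, 0.06 * is_ref),
                                 cal1_area, is_ref)$passed)
  expect_error(selectivity_check(blank_row(0), 0, is_ref), "positive")
})

test_that("crosstalk splits its verdict between the two channels", {
  cal1 <- meas_row(role = "calibrator", nominal_ug_ml = 0.05,
                   analyte_area = 1000, is_area = 5000)
  mk <- function(analyte_frac, is_frac) {
    list(cal0 = meas_row(role = "blank", analyte_area = analyte_frac * 1000,
                         is_area = 5000),
         cal6 = meas_row(role = "double_blank", day = 2,
                         analyte_area = 9e5, is_area = is_frac * 5000))
  }
  zero <- mk(0, 0)
  res <- crosstalk_check(zero$cal0, zero$cal6, cal1)
  expect_true(res$is_in_analyte$passed && res$analyte_in_is$passed)
  expect_equal(res$is_in_analyte$statistic_pct, 0)

  ok <- mk(0.10, 0.01)
  res2 <- crosstalk_check(ok$cal0, ok$cal6, cal1)
  expect_true(res2$is_in_analyte$passed && res2$analyte_in_is$passed)

  # 21% in the analyte channel fails; 1% in the IS channel still passes
  split <- mk(0.21, 0.01)
  res3 <- crosstalk_check(split$cal0, split$cal6, cal1)
  expect_false(res3$is_in_analyte$passed)
  expect_true(res3$analyte_in_is$passed)
  expect_equal(res3$is_in_analyte$statistic_pct, 21)

  # inclusive boundaries: exactly 20% / exactly 5% pass
  edge <- mk(0.20, 0.05)
  res4 <- crosstalk_check(edge$cal0, edge$cal6, cal1)
  expect_true(res4$is_in_analyte$passed && res4$analyte_in_is$passed)

  expect_error(crosstalk_check(NULL, zero$cal6, cal1), "CAL0")
})

test_that("carryover scores the worst of the trailing blanks inclusively", {
  cal1 <- meas_row(role = "calibrator", nominal_ug_ml = 0.05,
                   analyte_area = 1000, is_area = 5000)
  blanks <- function(fracs) {
    do.call(rbind, lapply(seq_along(fracs), function(i) {
      meas_row(role = "blank", replicate = i,
               analyte_area = fracs[i] * 1000, is_area = NA)
    }))
  }
  expect_true(carryover_check(blanks(c(0, 0, 0)), cal1)$passed)
  r14 <- carryover_check(blanks(c(0.14, 0.02, 0.01)), cal1)
  expect_true(r14$passed)
  expect_equal(r14$statistic_pct, 14)
  r25 <- carryover_check(blanks(c(0.25, 0.1, 0.02)), cal1)
  expect_false(r25$passed)
  expect_equal(r25$statistic_pct, 25)
  # inclusive at the configured limit
  expect_true(carryover_check(blanks(c(0.20)), cal1)$passed)
  expect_error(carryover_check(blanks(numeric(0)), cal1), "at least one")
})

test_that("stability deviations are scored against nominal with a passing duration", {
  fit <- fit_calibration(exact_calibrators(c(0, 1, 0)),
                         calibration_spec("linear", "log_log"))
  mk_series <- function(decay) {
    grid <- expand.grid(conc = c(0.1, 0.5, 2), time_h = c(0, 2, 4, 6, 24, 48, 72))
    as_measurements(data.frame(
      analyte = "IVA", role = "stability", day = 1, replicate = 1,
      nominal_ug_ml = grid$conc,
      analyte_area = grid$conc * (1 - decay * grid$time_h) * 1e5,
      is_area = 1e5, matrix = "plasma", temperature = "rt",
      time_h = grid$time_h))
  }
  stable <- stability_assessment(mk_series(0), fit = fit)[[1]]
  expect_true(stable$passed)
  expect_equal(stable$longest_passing_h, 72)
  expect_equal(stable$detail$dev_pct[stable$detail$time_h == 0], 0)

  decayed <- stability_assessment(mk_series(0.01), fit = fit)[[1]]
  d <- decayed$detail
  expect_equal(d$dev_pct[d$time_h == 6], -6, tolerance = 1e-9)
  expect_equal(d$dev_pct[d$time_h == 24], -24, tolerance = 1e-9)
  expect_false(d$passed[d$time_h == 24])
  expect_equal(decayed$longest_passing_h, 6)
  expect_equal(decayed$first_failing_h, 24)

  no_t0 <- mk_series(0)
  expect_error(stability_assessment(no_t0[no_t0$time_h > 0, ], fit = fit),
               "t = 0")
})

test_that("freeze-thaw compares cycles with the cycle-0 reference", {
  fit <- fit_calibration(exact_calibrators(c(0, 1, 0)),
                         calibration_spec("linear", "log_log"))
  mk_cycles <- function(devs) {  # per-cycle fractional deviation, cycles 1..3
    grid <- expand.grid(conc = c(0.1, 0.5, 2), cycle = 0:3)
    shift <- c(1, 1 + devs)[grid$cycle + 1]
    as_measurements(data.frame(
      analyte = "IVA", role = "stability", day = 1, replicate = 1,
      nominal_ug_ml = grid$conc, analyte_area = grid$conc * shift * 1e5,
      is_area = 1e5, cycle = grid$cycle))
  }
  same <- freeze_thaw_assessment(mk_cycles(c(0, 0, 0)), fit = fit)
  expect_true(same$passed)
  expect_equal(same$detail$dev_pct, rep(0, 3), tolerance = 1e-9)

  # worst mean deviation 12.2% still passes the +/-15% limit
  ok <- freeze_thaw_assessment(mk_cycles(c(0.05, -0.122, 0.08)), fit = fit)
  expect_true(ok$passed)
  expect_equal(max(abs(ok$detail$dev_pct)), 12.2, tolerance = 1e-6)

  bad <- freeze_thaw_assessment(mk_cycles(c(0.02, -0.16, 0.01)), fit = fit)
  expect_false(bad$passed)
  expect_error(freeze_thaw_assessment(mk_cycles(c(0, 0, 0))[-(1:3), ],
                                      fit = fit), "cycle-0")
})

test_that("dilution integrity recovers the nominal through the declared factor", {
  fit <- fit_calibration(exact_calibrators(c(0, 1, 0)),
                         calibration_spec("linear", "log_log"))
  mk_dil <- function(nominal, reading, lot = "L1", dilution = 10) {
    meas_row(role = "dilution_qc", nominal_ug_ml = nominal,
             analyte_area = reading * 1e5, is_area = 1e5, lot = lot,
             dilution = dilution)
  }
  exact <- dilution_integrity(mk_dil(10, 1), fit)
  expect_true(exact$passed)
  expect_equal(exact$statistic_pct, 0, tolerance = 1e-9)

  ten_pct <- dilution_integrity(mk_dil(20, 2.2), fit)
  expect_true(ten_pct$passed)
  expect_equal(ten_pct$statistic_pct, 10, tolerance = 1e-9)

  five_lots <- do.call(rbind, lapply(1:5, function(i) {
    mk_dil(10, 1 * (1 + c(-0.1, 0.05, 0.14, -0.15, 0.02)[i]),
           lot = paste0("L", i))
  }))
  res <- dilution_integrity(five_lots, fit)
  expect_true(res$passed)  # +/-15% inclusive
  expect_equal(nrow(res$detail), 5)

  # a diluted reading above the calibration range defeats the check
  expect_error(dilution_integrity(mk_dil(100, 8), fit), "outside")
})

test_that("inter-laboratory bias is inclusive at +/-15% and excludes unpaired", {
  same <- ilc_compare(c(10, 5), c(10, 5))
  expect_true(same$passed)
  expect_equal(same$statistic_pct, 0)

  edge <- ilc_compare(10.0, 11.5)
  expect_true(edge$passed)
  expect_equal(edge$statistic_pct, 15)

  over <- ilc_compare(10.0, 12.0)
  expect_false(over$passed)
  expect_equal(over$statistic_pct, 20)

  mixed <- ilc_compare(c(10, 8, NA), c(11, NA, 9),
                       lab = c("B", "B", "C"))
  expect_equal(sum(mixed$detail$paired), 1)
  expect_equal(mixed$lab_summary$mean_bias_pct, 10)
  expect_error(ilc_compare(NA_real_, 5), "no complete")
})

test_that("the dilution series yields the smallest detectable concentration", {
  cfg <- validation_config()
  series <- data.frame(factor = c(1, 2, 10), sn = c(90, 45, 9))
  res <- lod_from_dilution(0.15, series, cfg)
  expect_equal(res$lod_ug_ml, 0.015)
  expect_equal(res$sn, 9)
  expect_lte(res$lod_ug_ml, 0.015)

  none <- lod_from_dilution(0.15, data.frame(factor = c(1, 2), sn = c(2, 1)),
                            cfg)
  expect_true(is.na(none$lod_ug_ml))

  # S/N proportional to concentration, crossing between members
  prop <- data.frame(factor = c(1, 2, 4, 8, 16), sn = 12 / c(1, 2, 4, 8, 16))
  res2 <- lod_from_dilution(1, prop, cfg)
  expect_equal(res2$lod_ug_ml, 0.25)  # last member still meeting S/N >= 3
  expect_equal(res2$sn, 3)
  expect_error(lod_from_dilution(0.15,
                                 data.frame(factor = c(2, 1), sn = c(1, 2))),
               "increasing")
})

test_that("check verdicts are recomputable from statistic and threshold alone", {
  cal1 <- meas_row(role = "calibrator", nominal_ug_ml = 0.05,
                   analyte_area = 1000, is_area = 5000)
  blanks <- meas_row(role = "blank", analyte_area = 140, is_area = NA)
  res <- carryover_check(blanks, cal1)
  recomputed <- abs(res$statistic_pct) <= res$threshold_pct
  expect_identical(res$passed, recomputed)
})

test_that("percentage checks are invariant to a common rescaling of areas", {
  cal1 <- function(s) meas_row(role = "calibrator", nominal_ug_ml = 0.05,
                               analyte_area = 1000 * s, is_area = 5000 * s)
  blanks <- function(s) meas_row(role = "blank", analyte_area = 140 * s,
                                 is_area = NA)
  a <- carryover_check(blanks(1), cal1(1))
  b <- carryover_check(blanks(1000), cal1(1000))
  expect_equal(a$statistic_pct, b$statistic_pct)
})
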