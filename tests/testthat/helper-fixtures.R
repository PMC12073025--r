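# Shared fixture builders: everything is generated in code at test time.

# one injection record with sensible defaults
meas_row <- function(analyte = "IVA", role = "qc", day = 1L, replicate = 1L,
                     nominal_ug_ml = NA_real_, analyte_area = NA_real_,
                     is_area = NA_real_, lot = NA, matrix = NA,
                     temperature = NA, time_h = NA_real_, cycle = NA,
                     dilution = NA_real_) {
  data.frame(analyte = analyte, role = role, day = day,
             replicate = replicate, nominal_ug_ml = nominal_ug_ml,
             analyte_area = analyte_area, is_area = is_area, lot = lot,
             matrix = matrix, temperature = temperature, time_h = time_h,
             cycle = cycle, dilution = dilution, stringsAsFactors = FALSE)
}

# noise-free calibrators following log(ratio) = a + b log C + c log C^2
exact_calibrators <- function(coeffs = c(0, 1, 0),
                              concs = c(0.05, 0.1, 0.2, 0.5, 1.25, 5),
                              replicates = 2, analyte = "IVA",
                              is_area = 1e5) {
  grid <- expand.grid(replicate = seq_len(replicates), conc = concs)
  lc <- log(grid$conc)
  ratio <- exp(coeffs[1] + coeffs[2] * lc + coeffs[3] * lc^2)
  as_measurements(data.frame(
    analyte = analyte, role = "calibrator", day = 1L,
    replicate = grid$replicate, nominal_ug_ml = grid$conc,
    analyte_area = ratio * is_area, is_area = is_area,
    stringsAsFactors = FALSE))
}

# brute-force inversion oracle: two-stage dense grid search over the
# concentration window, independent of the analytic inversion
grid_invert <- function(fit, ratio) {
  lo <- 0.5 * fit$range[1]; hi <- 2 * fit$range[2]
  grid <- exp(seq(log(lo), log(hi), length.out = 1e6))
  i <- which.min(abs(predict(fit, grid) - ratio))
  fine <- exp(seq(log(grid[max(1, i - 2)]), log(grid[min(1e6, i + 2)]),
                  length.out = 2001))
  fine[which.min(abs(predict(fit, fine) - ratio))]
}

# balanced two-level values with exactly prescribed sample statistics
# (grand mean, repeatability SD, intermediate-precision SD), p = n = 3
exact_stat_values <- function(grand, s_r, s_ip, p = 3, n = 3) {
  stopifnot(p == 3, n == 3, s_ip >= s_r)
  ms_w <- s_r^2
  s_b2 <- s_ip^2 - s_r^2
  ms_b <- ms_w + n * s_b2
  day_means <- grand + sqrt(ms_b / n) * c(-1, 0, 1)  # sample SD of c(-1,0,1) is 1
  resid <- sqrt(ms_w * p * (n - 1) / (2 * p)) * c(-1, 0, 1)
  data.frame(day = rep(1:3, each = 3),
             value = rep(day_means, each = 3) + rep(resid, times = 3))
}
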