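test_that("variance components match hand-computed ANOVA on tiny fixtures", {
  # two days, duplicates: {(10,10),(12,12)} -> MS_within 0, day means 10/12
  vc <- variance_components(c(10, 10, 12, 12), day = c(1, 1, 2, 2))
  expect_equal(vc$ms_within, 0)
  expect_equal(vc$s_within, 0)
  expect_equal(vc$s_between, sqrt(2))
  expect_equal(vc$grand_mean, 11)

  # all identical -> both components vanish
  vc0 <- variance_components(rep(7, 9), day = rep(1:3, each = 3))
  expect_equal(vc0$s_within, 0)
  expect_equal(vc0$s_between, 0)

  # worked 2x2 with within-day spread: days {(9,11),(13,15)}
  # MS_within = ((9-10)^2+(11-10)^2+(13-14)^2+(15-14)^2)/2 = 2
  # MS_between = 2*((10-12)^2+(14-12)^2)/1 = 16 -> s_b^2 = (16-2)/2 = 7
  vc2 <- variance_components(c(9, 11, 13, 15), day = c(1, 1, 2, 2))
  expect_equal(vc2$ms_within, 2)
  expect_equal(vc2$ms_between, 16)
  expect_equal(vc2$s_between, sqrt(7))

  expect_error(variance_components(c(1, 2, 3), day = c(1, 1, 1)),
               "single day")
  expect_error(variance_components(c(1, 2), day = c(1, 2)),
               "one replicate per day")
})

test_that("negative moment estimates of between-day variance clamp to zero", {
  # day means closer than the within-day noise predicts
  vc <- variance_components(c(9, 11, 10.1, 9.9), day = c(1, 1, 2, 2))
  expect_true(vc$ms_between < vc$ms_within)
  expect_equal(vc$s_between, 0)
  expect_equal(vc$s_ip, vc$s_within)
})

test_that("Monte-Carlo recovery of variance components on the variance scale", {
  set.seed(2026)
  p <- 3; n <- 3
  s_b <- 3; s_w <- 4
  est <- replicate(2000, {
    x <- rep(rnorm(p, 0, s_b), each = n) + rnorm(p * n, 0, s_w)
    vc <- variance_components(x, rep(seq_len(p), each = n))
    c(w2 = vc$s_within^2, ip2 = vc$s_ip^2)
  })
  expect_lt(abs(sqrt(mean(est["w2", ])) / s_w - 1), 0.05)
  expect_lt(abs(sqrt(mean(est["ip2", ])) / sqrt(s_b^2 + s_w^2) - 1), 0.05)
})

test_that("the tolerance interval collapses to the bias at zero variance", {
  des <- tolerance_design(3, 3, 0.80)
  ti <- beta_expectation_interval(-4.2, 0, 0, des)
  expect_equal(as.numeric(ti), c(-4.2, -4.2))
  expect_equal(measurement_uncertainty(0, 0, tolerance_design(3, 3, 0.95)), 0)
})

test_that("interval bounds always bracket the bias and s_ip >= s_r", {
  set.seed(31)
  des <- tolerance_design(3, 3, 0.80)
  for (i in 1:200) {
    bias <- runif(1, -20, 20)
    s_w <- runif(1, 0, 10); s_b <- runif(1, 0, 10)
    ti <- beta_expectation_interval(bias, s_w, s_b, des)
    expect_true(ti[1] <= bias && bias <= ti[2])
    expect_gte(sqrt(s_w^2 + s_b^2), s_w)
  }
})

test_that("interval width is nonincreasing in the number of days and replicates", {
  for (s_b in c(0.5, 3, 8)) {
    w_p <- vapply(2:8, function(p) {
      diff(beta_expectation_interval(0, 4, s_b, tolerance_design(p, 3)))
    }, numeric(1))
    expect_true(all(diff(w_p) <= 1e-12))
    w_n <- vapply(1:8, function(n) {
      diff(beta_expectation_interval(0, 4, s_b, tolerance_design(3, n)))
    }, numeric(1))
    expect_true(all(diff(w_n) <= 1e-12))
  }
})

test_that("with no between-day component the interval matches the one-sample form", {
  for (beta in c(0.80, 0.95)) {
    des <- tolerance_design(3, 3, beta)
    ti <- beta_expectation_interval(0, 5, 0, des)
    one_sample <- qt((1 + beta) / 2, df = 3 * 3 - 1) *
      sqrt(1 + 1 / (3 * 3)) * 5
    expect_equal(unname(ti[2]), one_sample, tolerance = 0.01)
  }
})

test_that("expanded uncertainty at 0.95 exceeds the 0.80 profile half-width", {
  half80 <- diff(beta_expectation_interval(0, 4, 3,
                                           tolerance_design(3, 3, 0.80))) / 2
  mu95 <- measurement_uncertainty(4, 3, tolerance_design(3, 3, 0.95))
  expect_gt(mu95, half80)
})

test_that("bias +/- MU covers about 95% of future measurements", {
  res <- simulate_tolerance_coverage(10000, tolerance_design(3, 3, 0.95),
                                     s_between_pct = 3, s_within_pct = 4,
                                     seed = 77)
  expect_lt(abs(res$coverage - 0.95), 0.02)
})

test_that("the zero-within-day limit uses the between-day degrees of freedom", {
  ti <- beta_expectation_interval(0, 0, 5, tolerance_design(4, 3, 0.80))
  expect_equal(attr(ti, "nu"), 3)  # p - 1
  expect_equal(attr(ti, "B2"), 1 / 3)
  expect_true(is.finite(ti[1]) && ti[2] > 0)
})
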