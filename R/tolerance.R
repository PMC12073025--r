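## One-way random-effects variance components and beta-expectation
## tolerance intervals (Mee-type, Satterthwaite degrees of freedom), the
## construction standardized by the SFSTP accuracy-profile guidance.
##
## For a balanced design with p series (days) and n replicates per series:
##   s_within^2  = MS_within
##   s_between^2 = max(0, (MS_between - MS_within) / n)      (moment repair)
##   s_IP^2      = s_within^2 + s_between^2
##   R  = s_between^2 / s_within^2,  B^2 = (R + 1) / (n R + 1)
##   nu = (R + 1)^2 / [ (R + 1/n)^2/(p - 1) + (1 - 1/n)/(p n) ]
##   interval = bias +/- t_{nu, (1+beta)/2} * sqrt(1 + 1/(p n B^2)) * s_IP

#' Tolerance-interval design
#'
#' @param p number of series (days), >= 2.
#' @param n replicates per series, >= 1.
#' @param beta coverage probability in (0, 1).
#' @return object of class `tolerance_design`.
#' @export
tolerance_design <- function(p, n, beta = 0.80) {
  p <- as.integer(p); n <- as.integer(n)
  stopifnot(p >= 2L, n >= 1L, is.numeric(beta), beta > 0, beta < 1)
  structure(list(p = p, n = n, beta = beta), class = "tolerance_design")
}

#' Variance components of one QC level
#'
#' Method-of-moments estimates from a one-way random-effects layout (days as
#' the random factor): repeatability (within-day), between-day and
#' intermediate-precision SDs. The design is assumed balanced; mild
#' imbalance is flagged with a warning and handled with the mean group size.
#'
#' @param values numeric measurements (back-calculated concentrations, or
#'   any common scale).
#' @param day grouping vector (one entry per value).
#' @return list with `s_within`, `s_between`, `s_ip`, `ms_within`,
#'   `ms_between`, `grand_mean`, `p`, `n`.
#' @export
variance_components <- function(values, day) {
  stopifnot(length(values) == length(day), length(values) >= 2L)
  ok <- !is.na(values) & !is.na(day)
  values <- values[ok]; day <- day[ok]
  groups <- split(values, day)
  p <- length(groups)
  if (p < 2L) {
    stop("intermediate precision undefined with a single day", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (all(sizes == 1L)) {
    stop("within-day variance inestimable with one replicate per day",
         call. = FALSE)
  }
  if (length(unique(sizes)) > 1L) {
    warning("unbalanced design: using the mean group size in the moment equations",
            call. = FALSE)
  }
  n <- mean(sizes)
  gm <- vapply(groups, mean, numeric(1))
  grand <- mean(values)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  ms_within <- ss_within / sum(sizes - 1L)
  ms_between <- sum(sizes * (gm - grand)^2) / (p - 1)
  s_w2 <- ms_within
  s_b2 <- max(0, (ms_between - ms_within) / n)
  list(s_within = sqrt(s_w2), s_between = sqrt(s_b2),
       s_ip = sqrt(s_w2 + s_b2), ms_within = ms_within,
       ms_between = ms_between, grand_mean = grand, p = p, n = n)
}

## interval multiplier k and Satterthwaite nu for given components;
## handles the degenerate corners (both variances zero; zero within-day).
tolerance_factor <- function(s_within, s_between, p, n, beta) {
  stopifnot(s_within >= 0, s_between >= 0)
  if (s_within == 0 && s_between == 0) {
    return(list(k = 0, nu = Inf, R = 0, B2 = 1))
  }
  if (s_within == 0) {          # R -> Inf limit
    B2 <- 1 / n
    nu <- p - 1
  } else {
    R <- s_between^2 / s_within^2
    B2 <- (R + 1) / (n * R + 1)
    nu <- (R + 1)^2 /
      ((R + 1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n))
  }
  if (p * n * B2 <= 0) stop("degenerate design: p*n*B^2 = 0", call. = FALSE)
  k <- qt((1 + beta) / 2, df = nu) * sqrt(1 + 1 / (p * n * B2))
  list(k = k, nu = nu,
       R = if (s_within == 0) Inf else s_between^2 / s_within^2, B2 = B2)
}

#' Beta-expectation tolerance interval
#'
#' Interval expected to contain a fraction beta of future individual
#' measurements, combining the systematic error (bias) with the
#' intermediate-precision spread inflated for the finite validation design.
#' All inputs and outputs are in percent of the nominal concentration.
#'
#' @param bias_pct estimated bias (mean relative error), percent.
#' @param s_within within-day (repeatability) SD, percent of nominal.
#' @param s_between between-day SD, percent of nominal.
#' @param design a [tolerance_design()].
#' @return numeric `c(tol_low_pct, tol_high_pct)` with attributes `nu`
#'   (Satterthwaite degrees of freedom), `R`, `B2` and `k` (the interval
#'   multiplier).
#' @examples
#' beta_expectation_interval(-2, 4, 3, tolerance_design(p = 3, n = 3))
#' @export
beta_expectation_interval <- function(bias_pct, s_within, s_between, design) {
  stopifnot(inherits(design, "tolerance_design"))
  tf <- tolerance_factor(s_within, s_between, design$p, design$n, design$beta)
  s_ip <- sqrt(s_within^2 + s_between^2)
  half <- tf$k * s_ip
  structure(c(tol_low_pct = bias_pct - half, tol_high_pct = bias_pct + half),
            nu = tf$nu, R = tf$R, B2 = tf$B2, k = tf$k)
}

#' Expanded measurement uncertainty
#'
#' Half-width of the beta-expectation interval at the measurement-uncertainty
#' coverage (by default 0.95), reported in percent of nominal. This is the
#' expanded uncertainty attached to a reported concentration, derived from
#' validation-phase variance components.
#'
#' @param s_within,s_between precision components in percent of nominal.
#' @param design a [tolerance_design()]; its `beta` should be the MU
#'   coverage (e.g. 0.95).
#' @return expanded uncertainty in percent of nominal (half-width).
#' @export
measurement_uncertainty <- function(s_within, s_between, design) {
  stopifnot(inherits(design, "tolerance_design"))
  tf <- tolerance_factor(s_within, s_between, design$p, design$n, design$beta)
  tf$k * sqrt(s_within^2 + s_between^2)
}

#' Monte-Carlo coverage of the tolerance interval
#'
#' Simulates balanced two-level normal datasets (`day effect ~ N(0,
#' s_between)`, `residual ~ N(0, s_within)`, both in percent of nominal),
#' computes the beta-expectation interval of each dataset, draws one future
#' measurement from the same model and reports the fraction of future
#' measurements falling inside their interval. Used to verify that the
#' interval construction attains its nominal expectation coverage.
#'
#' @param n_sim number of simulated datasets.
#' @param design a [tolerance_design()].
#' @param s_between_pct,s_within_pct generating SDs, percent of nominal.
#' @param bias_pct generating bias, percent.
#' @param seed optional integer seed.
#' @return list with `coverage` (fraction in `[0, 1]`), `mean_width_pct` and
#'   `n_sim`.
#' @export
simulate_tolerance_coverage <- function(n_sim, design,
                                        s_between_pct = 3, s_within_pct = 4,
                                        bias_pct = 0, seed = NULL) {
  stopifnot(inherits(design, "tolerance_design"), n_sim >= 1L)
  if (!is.null(seed)) set.seed(seed)
  p <- design$p; n <- design$n; N <- p * n

  day_eff <- matrix(rnorm(n_sim * p, 0, s_between_pct), n_sim, p)
  x <- bias_pct + day_eff[, rep(seq_len(p), each = n)] +
    matrix(rnorm(n_sim * N, 0, s_within_pct), n_sim, N)

  day_idx <- rep(seq_len(p), each = n)
  day_means <- vapply(seq_len(p), function(d) {
    rowMeans(x[, day_idx == d, drop = FALSE])
  }, numeric(n_sim))
  grand <- rowMeans(x)
  ms_within <- rowSums((x - day_means[, day_idx, drop = FALSE])^2) /
    (p * (n - 1))
  ms_between <- n * rowSums((day_means - grand)^2) / (p - 1)
  s_w2 <- ms_within
  s_b2 <- pmax(0, (ms_between - ms_within) / n)
  s_ip <- sqrt(s_w2 + s_b2)

  R <- ifelse(s_w2 > 0, s_b2 / s_w2, Inf)
  B2 <- ifelse(is.finite(R), (R + 1) / (n * R + 1), 1 / n)
  nu <- ifelse(is.finite(R),
               (R + 1)^2 / ((R + 1 / n)^2 / (p - 1) + (1 - 1 / n) / (p * n)),
               p - 1)
  k <- qt((1 + design$beta) / 2, df = nu) * sqrt(1 + 1 / (p * n * B2))
  half <- k * s_ip

  future <- bias_pct + rnorm(n_sim, 0, s_between_pct) +
    rnorm(n_sim, 0, s_within_pct)
  inside <- future >= grand - half & future <= grand + half
  list(coverage = mean(inside), mean_width_pct = mean(2 * half),
       n_sim = n_sim)
}
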