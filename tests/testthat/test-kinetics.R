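# Enzymology: initial rates, kcat/Km efficiency, site ratios, one-phase
# decay half-lives, efficiency-ratio regression.

test_that("initial rate on an exact line is the slope with zero SE", {
  cv <- progress_curve(0:10, 2 * (0:10))
  r <- initial_rate(cv)
  expect_equal(r$rate, 2)
  expect_equal(r$se, 0, tolerance = 1e-10)
  expect_error(initial_rate(progress_curve(0:2, c(0, 1, 2)),
                            window = c(0, 1)), "data error")
})

test_that("early-window rate of a noiseless exponential matches the t=0 derivative", {
  k <- 1e3 * 0.2e-6       # (kcat/Km) * E, per second
  S0 <- 10e-6
  t <- seq(0, 5000, by = 10)
  cv <- progress_curve(t, S0 * (1 - exp(-k * t)), signal_unit = "M")
  r <- initial_rate(cv, S0 = S0, max_conversion = 0.02)
  expect_equal(r$rate, k * S0, tolerance = 0.02)
})

test_that("recovered initial rates are unbiased under multiplicative noise", {
  k_true <- 1e3 * 0.2e-6
  S0 <- 10e-6
  rates <- vapply(1:50, function(s) {
    sim <- simulate_progress_curves(1e3, 0.2e-6, S0,
                                    timepoints = seq(0, 600, by = 25),
                                    noise_frac = 0.02, n_replicates = 1,
                                    seed = s)
    initial_rate(sim$curves[[1]], S0 = S0, max_conversion = 0.06)$rate
  }, numeric(1))
  # mean recovered rate within 5% of the true initial slope
  expect_equal(mean(rates), k_true * S0, tolerance = 0.05)
})

test_that("estimate_efficiency inverts the generative formula exactly", {
  kk <- 1e4
  E <- 0.2e-6; S0 <- 10e-6; t <- 3 * 3600
  P <- S0 * (1 - exp(-kk * E * t))
  est <- estimate_efficiency(P, E, S0, t)
  expect_equal(est$kcat_over_Km, kk, tolerance = 1e-8)
  expect_equal(est$sd, 0)
  # small-conversion limit agrees with rate/(E*S0)
  t0 <- 1
  P0 <- S0 * (1 - exp(-kk * E * t0))
  expect_equal(estimate_efficiency(P0, E, S0, t0)$kcat_over_Km,
               (P0 / t0) / (E * S0), tolerance = 0.01)
  # scale consistency: doubling E and halving t leaves the estimate fixed
  expect_equal(estimate_efficiency(P, 2 * E, S0, t / 2)$kcat_over_Km,
               est$kcat_over_Km)
  expect_error(estimate_efficiency(S0, E, S0, t), "saturation")
  expect_error(estimate_efficiency(-1e-9, E, S0, t), "data error")
})

test_that("triplicate noisy endpoints give a nearly unbiased efficiency with reported s.d.", {
  kk <- 1e3; E <- 0.2e-6; S0 <- 10e-6; t <- 3600
  P_ideal <- S0 * (1 - exp(-kk * E * t))
  means <- vapply(1:100, function(s) {
    set.seed(s)
    P <- pmin(P_ideal * (1 + rnorm(3, sd = 0.03)), S0 * 0.9999)
    est <- estimate_efficiency(P, E, S0, t)
    expect_gte(est$sd, 0)
    est$kcat_over_Km
  }, numeric(1))
  expect_lt(abs(mean(means) - kk) / kk, 0.03)
})

test_that("site ratios and their propagated uncertainties are correct", {
  t <- 1:6
  den <- progress_curve(t, c(10, 20, 30, 40, 50, 60))
  expect_equal(site_ratio(den, den, noise_sd = 0.5)$ratio, rep(1, 6))
  num <- progress_curve(t, 2 * den$signal)
  sr <- site_ratio(num, den, noise_sd = 0.5)
  expect_equal(sr$ratio, rep(2, 6))
  # denominator below 3x the noise floor is flagged undefined
  den2 <- progress_curve(t, c(1, 20, 30, 40, 50, 60))
  sr2 <- site_ratio(num, den2, noise_sd = 0.5)
  expect_false(sr2$defined[1])
  expect_true(is.na(sr2$ratio[1]))
  expect_error(site_ratio(num, progress_curve(t + 0.5, den$signal), 0.5),
               "matched timepoints")
})

test_that("first-order ratio uncertainty matches Monte-Carlo propagation", {
  noise <- 2
  n_true <- 80; d_true <- 40
  sr <- site_ratio(progress_curve(1:2, c(n_true, n_true)),
                   progress_curve(1:2, c(d_true, d_true)), noise)
  set.seed(77)
  draws <- (n_true + rnorm(1e4, sd = noise)) /
    (d_true + rnorm(1e4, sd = noise))
  expect_equal(sr$sd[1], sd(draws), tolerance = 0.1)
})

test_that("noiseless one-phase decay is fitted exactly", {
  t <- seq(0, 24, by = 0.5)
  y <- 100 * exp(-(log(2) / 4) * t) + 10
  fit <- fit_one_phase_decay(t, y, t_chx = 0)
  expect_equal(fit$half_life, 4, tolerance = 1e-6)
  expect_equal(fit$plateau, 10, tolerance = 1e-4)
  expect_equal(fit$Y0, 110, tolerance = 1e-4)
  # scaling the series leaves the half-life unchanged
  fit2 <- fit_one_phase_decay(t, 7.3 * y, t_chx = 0)
  expect_equal(fit2$half_life, fit$half_life, tolerance = 1e-9)
})

test_that("constant or insufficient series raise decay errors", {
  t <- seq(0, 10, by = 1)
  expect_error(fit_one_phase_decay(t, rep(50, length(t))), "no-decay")
  expect_error(fit_one_phase_decay(0:3, c(4, 3, 2, 1)), "data error")
  expect_error(fit_one_phase_decay(t, rep(-1, length(t))), "data error")
})

test_that("fitting starts at treatment time and ends at the plateau minimum", {
  sim <- simulate_decay(t_half = 3.5, t_chx = 2, noise_frac = 0,
                        n_replicates = 1, seed = 1)
  d <- sim$table[sim$table$replicate == 1, ]
  fit <- fit_one_phase_decay(d$time_hr, d$signal, t_chx = 2)
  expect_equal(fit$half_life, 3.5, tolerance = 1e-6)
  expect_gte(fit$fit_window[1], 2)
})

test_that("half-life recovery under 2% noise is within 5% in the median", {
  hl <- vapply(1:200, function(s) {
    sim <- simulate_decay(t_half = 3.5, noise_frac = 0.02,
                          n_replicates = 1, seed = s)
    d <- sim$table
    fit_one_phase_decay(d$time_hr, d$signal, t_chx = 2)$half_life
  }, numeric(1))
  expect_lt(abs(median(hl) - 3.5) / 3.5, 0.05)
})

test_that("decay recovery bias shrinks as noise decreases", {
  bias_at <- function(noise) {
    hl <- vapply(1:60, function(s) {
      d <- simulate_decay(t_half = 3.5, noise_frac = noise,
                          n_replicates = 1, seed = s)$table
      fit_one_phase_decay(d$time_hr, d$signal, t_chx = 2)$half_life
    }, numeric(1))
    abs(median(hl) - 3.5)
  }
  expect_lt(bias_at(0.005), bias_at(0.08) + 1e-9)
})

test_that("regression on exact collinear data reproduces the coefficients", {
  x <- c(0.5, 1, 1.5, 2, 2.5)
  fit <- efficiency_halflife_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$slope_ci[1] <= fit$slope & fit$slope <= fit$slope_ci[2])
  expect_error(efficiency_halflife_regression(1, 2), "data error")
  expect_error(efficiency_halflife_regression(c(1, 2), c(1, 2)),
               "data error")
})

test_that("slope confidence intervals achieve nominal coverage", {
  hits <- vapply(1:400, function(s) {
    sim <- simulate_phosphoswitch_panel(slope = 1.5, n_mutants = 8,
                                        noise_sd = 0.3, seed = s)
    fit <- efficiency_halflife_regression(sim$table$ratio,
                                          sim$table$half_life_hr)
    fit$slope_ci[1] <= 1.5 && 1.5 <= fit$slope_ci[2]
  }, logical(1))
  # 95% CI should cover the truth about 95% of the time (binomial s.e.
  # at n=400 is ~1.1%, test at 3 sigma)
  expect_gt(mean(hits), 0.95 - 0.033)
  expect_lt(mean(hits), 0.95 + 0.033)
})
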