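test_that("background correction subtracts, clips at zero and warns", {
  s <- efflux_series(c(0, 20), c(100, 60), c(10, 10))
  expect_equal(background_correct(s), c(90, 50))
  s0 <- efflux_series(c(0, 20), c(100, 60))
  expect_equal(background_correct(s0), c(100, 60))
  s_neg <- efflux_series(c(0, 20), c(100, 5), c(10, 10))
  expect_warning(out <- background_correct(s_neg), "clipped")
  expect_equal(out, c(90, 0))
  expect_error(efflux_series(c(0, 20), c(1, 2, 3), c(0, 0)), "equal length")
})

test_that("an exact exponential recovers its rate constant to 1e-10", {
  t_s <- c(0, 20, 40, 60, 80)
  for (k in c(0.40, 0.15, 1.2)) {
    s <- efflux_series(t_s, 1e4 * exp(-k * t_s / 60))
    fit <- efflux_rate_constant(s)
    expect_equal(fit$rate_constant_per_min, k, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
  # constant series has rate constant zero
  flat <- efflux_series(t_s, rep(500, 5))
  expect_equal(efflux_rate_constant(flat)$rate_constant_per_min, 0,
               tolerance = 1e-12)
})

test_that("efflux regression matches the normal-equations oracle", {
  s <- simulate_efflux(k_per_min = 0.40, seed = 3)
  fit <- efflux_rate_constant(s)
  a <- suppressWarnings(background_correct(s))
  oracle <- ols_oracle(s$time_s / 60, log(a / a[1]))
  expect_equal(fit$rate_constant_per_min, -oracle$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
})

test_that("Poisson-noise replicates recover the bumetanide rate unbiasedly", {
  k <- vapply(seq_len(300), function(i) {
    s <- simulate_efflux(k_per_min = 0.15, a0 = 10000, seed = 2000 + i)
    efflux_rate_constant(s)$rate_constant_per_min
  }, numeric(1))
  se_mean <- stats::sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - 0.15), 2 * se_mean + 0.002)
})

test_that("non-positive corrected activity is rejected with its time points", {
  s <- efflux_series(c(0, 20, 40), c(100, 10, 10), c(0, 10, 0))
  expect_error(efflux_rate_constant(s), "20")
})

test_that("linear rates are extracted with unit handling", {
  t_min <- seq(0, 5, 0.5)
  y <- 1 + 0.12 * t_min
  fit <- rate_from_series(t_min, y)
  expect_equal(fit$slope_per_min, 0.12, tolerance = 1e-12)
  # seconds input is converted to per-minute
  fit_s <- rate_from_series(t_min * 60, y, time_unit = "s")
  expect_equal(fit_s$slope_per_min, 0.12, tolerance = 1e-12)
  expect_equal(rate_from_series(t_min, rep(2, length(t_min)))$slope_per_min, 0)
  expect_error(rate_from_series(rep(1, 5), 1:5), "singular")
})

test_that("noisy imaging series recover their slope within 3 SE", {
  t_min <- seq(0, 5, 0.5)
  set.seed(9)
  y <- 1 + 0.16 * t_min + rnorm(length(t_min), 0, 0.05)
  fit <- rate_from_series(t_min, y)
  expect_lt(abs(fit$slope_per_min - 0.16), 3 * fit$slope_se_per_min)
})

test_that("noiseless Hill curves are recovered exactly", {
  for (truth in list(c(ic50 = 10.7, hill = 1), c(ic50 = 4.5, hill = 1),
                     c(ic50 = 2, hill = 0.5), c(ic50 = 50, hill = 3))) {
    d <- simulate_dose_response(ic50 = truth["ic50"], hill = truth["hill"],
                                y_min = 5, y_max = 95, noise_sd = 0)
    fit <- hill_fit(d$dose_um, d$response)
    expect_equal(fit$ic50, unname(truth["ic50"]), tolerance = 1e-6)
    expect_equal(fit$hill_slope, unname(truth["hill"]), tolerance = 1e-6)
    expect_equal(fit$y_min, 5, tolerance = 1e-5)
    expect_equal(fit$y_max, 95, tolerance = 1e-5)
  }
})

test_that("Hill fit agrees with a grid-search oracle on a small instance", {
  d <- simulate_dose_response(ic50 = 10.7, hill = 1, y_min = 2, y_max = 90,
                              noise_sd = 1.5, seed = 21)
  fit <- hill_fit(d$dose_um, d$response)
  oracle <- hill_oracle(d$dose_um, d$response,
                        ic50_grid = exp(seq(log(1), log(100), length.out = 400)),
                        hill_grid = seq(0.5, 2, 0.025))
  expect_equal(fit$ic50, oracle$ic50, tolerance = 0.05)
  expect_equal(fit$hill_slope, oracle$hill, tolerance = 0.05)
})

test_that("degenerate dose-response inputs are rejected informatively", {
  expect_error(hill_fit(c(1, 2, 4), c(1, 2, 3)), "at least 4")
  expect_error(hill_fit(c(1, 3, 10, 30), rep(5, 4)), "flat response")
  expect_error(hill_fit(c(-1, 3, 10, 30), c(1, 2, 3, 4)), "positive")
})
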