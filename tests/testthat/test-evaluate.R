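test_that("AAFE matches its algebraic identities", {
  m <- c(3, 50, 700)
  expect_equal(aafe(m, m), 1)
  expect_equal(aafe(2 * m, m), 2)
  expect_equal(aafe(c(10, 1000), c(100, 100)), 10)
  # symmetry and multiplicative invariance
  s <- c(5, 40, 900)
  expect_equal(aafe(s, m), aafe(m, s))
  expect_equal(aafe(17 * s, 17 * m), aafe(s, m))
  expect_gte(aafe(s, m), 1)
  expect_error(aafe(c(1, -1), c(1, 1)), "positive")
  expect_error(aafe(1:3, 1:2), "equal length")
})

test_that("relative error is the absolute percent deviation", {
  expect_equal(relative_error(158, 158), 0)
  expect_equal(relative_error(120, 100), 20)
  expect_equal(relative_error(50, 100), 50)
  expect_error(relative_error(1, 0), "measured")
})

test_that("R-squared behaves in linear and log10 space", {
  m <- c(1, 10, 100, 1000)
  expect_equal(r_squared(m, m), 1)
  expect_equal(r_squared(3 * m + 2, m, space = "linear"), 1)
  # squaring makes the orientation irrelevant: a perfect negative linear
  # relation scores the same as a perfect positive one
  expect_equal(r_squared(-3 * m + 5000, m, space = "linear"), 1)
  expect_error(r_squared(c(1, -1, 2), c(1, 2, 3)), "positive")
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("fold-band fraction counts points within 0.5x to 2x", {
  m <- c(4, 4, 4, 4)
  expect_equal(fold_band_fraction(m, m), 1)
  expect_equal(fold_band_fraction(3 * m, m), 0)
  expect_equal(fold_band_fraction(c(0.4, 1.0, 1.9, 2.5) * m, m), 0.5)
})

test_that("half-life recovers exponential decay and flags its absence", {
  tt <- seq(0, 700, by = 1)
  k <- log(2) / 100
  hl <- half_life(data.frame(time = tt, mass = 20 * exp(-k * tt)))
  expect_equal(hl$t_half, 100, tolerance = 1e-9)
  expect_identical(hl$status, "ok")
  # scale invariance
  hl2 <- half_life(data.frame(time = tt, mass = 7e3 * exp(-k * tt)))
  expect_equal(hl2$t_half, hl$t_half)
  # constant series has no elimination phase
  hl3 <- half_life(data.frame(time = tt, mass = rep(5, length(tt))))
  expect_identical(hl3$status, "no elimination")
  expect_true(is.na(hl3$t_half))
  expect_error(half_life(data.frame(time = 0:10, mass = rep(1, 11)),
                         window = c(700, 800)), "fewer than 2")
})

test_that("log-log sensitivity matches closed forms", {
  # power law y = theta^2 -> S = 2 at all outputs
  expect_equal(log_log_sensitivity(function(th) rep(th^2, 4), 3),
               rep(2, 4), tolerance = 1e-10)
  # output independent of theta -> 0
  expect_equal(log_log_sensitivity(function(th) c(5, 6), 3), c(0, 0))
  # one-compartment decay y = exp(-k t): d ln y / d ln k = -k t
  # (k*t kept small so the O(h^2) truncation error stays below 1e-4)
  tt <- c(1, 5, 10)
  k <- 0.3
  S <- log_log_sensitivity(function(kk) exp(-kk * tt), k)
  expect_lt(max(abs(S - (-k * tt))), 1e-4)
  expect_error(log_log_sensitivity(identity, -1), "theta")
})

test_that("model-based sensitivity is smooth in the step size", {
  p <- default_parameters()
  sc <- kreyling_preset()$scenario
  s1 <- local_sensitivity(p, sc, "respiratory.P_lu", "liver",
                          times = c(24, 168), h = 0.01)
  s2 <- local_sensitivity(p, sc, "respiratory.P_lu", "liver",
                          times = c(24, 168), h = 0.005)
  expect_lt(max(abs(s1$S - s2$S) / abs(s2$S)), 0.01)
  expect_identical(s1$rule, "max_abs")
  expect_equal(unname(s1$aggregate["liver"]), max(abs(s1$S)))
})

test_that("perturbation study returns baseline-anchored fold changes", {
  p <- default_parameters()
  sc <- kreyling_preset()$scenario
  # the upper airway starts empty in this scenario, so its clearance rate
  # has structurally zero influence on every trajectory
  pert <- perturbation_study(p, sc, "respiratory.K_upp_feces",
                             factors = c(0.5, 2),
                             outputs = "tracheobronchial", t_end = 10)
  d <- pert$data
  # unit factor reproduces the baseline exactly
  expect_true(all(d$fold_change[d$factor == 1] == 1, na.rm = TRUE))
  for (f in c(0.5, 2))
    expect_identical(d$mass[d$factor == f], d$mass[d$factor == 1])
  expect_error(perturbation_study(p, sc, "chemical.rob.K_50", factors = -1,
                                  outputs = "lung", t_end = 5), "factors")
})

test_that("calibration recovers a displaced parameter on noise-free data", {
  p <- default_parameters()
  pre <- kreyling_preset()
  pre$obs_times <- c(4, 24, 96, 168)
  obs <- generate_observed(p, pre, noise_cv = 0, replicates = 1, seed = 1,
                           dt = 0.5)
  truth <- get_parameter(p, "respiratory.P_lu")
  start <- set_parameter(p, "respiratory.P_lu", 2 * truth)
  fit <- fit_parameters(start, pre$scenario, obs,
                        free = "respiratory.P_lu", dt = 0.5)
  expect_lt(abs(fit$estimates[["respiratory.P_lu"]] - truth) / truth, 0.01)
  expect_lt(fit$objective, 1e-8)
  expect_equal(fit$convergence, 0L)

  # starting at the truth the objective is already (numerically) zero
  fit0 <- fit_parameters(p, pre$scenario, obs, free = character(0))
  expect_identical(flatten_parameters(fit0$params), flatten_parameters(p))
  expect_lt(fit0$objective, 1e-12)
})

test_that("observed datasets survive a CSV round trip", {
  d <- data.frame(observable = c("lung", "liver"), time_h = c(4, 24),
                  mean_ng = c(600.25, 7.125), sd_ng = c(30.5, 0.75))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observed(d, path)
  expect_equal(read_observed(path), d)
  bad <- d; names(bad)[3] <- "value"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_observed(path), "lacks columns")
})
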