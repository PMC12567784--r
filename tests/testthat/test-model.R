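test_that("Hill uptake rate has the half-maximum, origin and saturation
           properties", {
  cases <- list(c(263.8254, 0.3592, 1), c(0.9929, 13.6432, 1),
                c(240, 1000, 2), c(5, 12, 0.7))
  for (cs in cases) {
    K_max <- cs[1]; K_50 <- cs[2]; n0 <- cs[3]
    expect_equal(hill_uptake_rate(K_max, K_50, n0, K_50), K_max / 2)
    expect_equal(hill_uptake_rate(K_max, K_50, n0, 0), 0)
    tt <- seq(0, 50 * K_50, length.out = 400)
    k <- hill_uptake_rate(K_max, K_50, n0, tt)
    expect_true(all(diff(k) >= 0))          # monotone non-decreasing
    expect_true(all(k >= 0 & k <= K_max))   # bounded
  }
  # saturation: far beyond K_50 the rate approaches K_max
  expect_equal(hill_uptake_rate(263.8254, 0.3592, 1, 1e9), 263.8254,
               tolerance = 1e-6)
  expect_error(hill_uptake_rate(1, 1, 1, -0.1), "t must be >= 0")
  expect_error(hill_uptake_rate(1, -1, 1, 0), "K_50")
})

test_that("organ fluxes decouple and vanish at partition equilibrium", {
  p <- default_parameters()
  for (key in c("X", "K_max", "K_out", "K_excrete"))
    p <- set_parameter(p, paste0("chemical.liver.", key), 0)
  y <- random_state()
  fl <- organ_fluxes("liver", y, p, t = 5)
  # tissue and PC pools are fully decoupled; capillary is wash-through only
  expect_equal(fl[["tis"]], 0)
  expect_equal(fl[["PCs"]], 0)
  ph <- p$physiological
  expect_equal(fl[["cab"]],
               ph$liver$Q * (y[["M_art"]] / ph$V_art -
                             y[["M_liver_cab"]] / ph$liver$V_cab))

  # with uptake off and C_tis = P * C_cab the exchange bracket vanishes
  p2 <- set_parameter(default_parameters(), "chemical.spleen.K_max", 0)
  ph <- p2$physiological$spleen
  ch <- p2$chemical$spleen
  y <- random_state()
  y["M_spleen_PCs"] <- 0
  y["M_spleen_tis"] <- ch$P * ph$V_tis * y[["M_spleen_cab"]] / ph$V_cab
  fl <- organ_fluxes("spleen", y, p2, t = 40)
  expect_equal(fl[["tis"]], 0)
  expect_equal(fl[["PCs"]], 0)

  expect_error(organ_fluxes("pancreas", y, p2, 0), "unknown organ")
})

test_that("an organ with no perfusion and no excretion conserves its mass", {
  p <- default_parameters()
  p <- set_parameter(p, "physiological.spleen.Q", 0)
  set.seed(11)
  for (i in 1:5) {
    fl <- organ_fluxes("spleen", random_state(), p, t = runif(1, 0, 600))
    expect_equal(sum(fl), 0, tolerance = 1e-12)
  }
})

test_that("respiratory fluxes respect the source term contract", {
  p <- default_parameters()
  bolus <- bolus_scenario(tra = 40, alv = 892)
  cont0 <- continuous_scenario(EC = 0, BR = 2, duration = 6,
                               FR = c(upp = 0.3, tra = 0.1, alv = 0.2))
  y <- random_state()
  expect_equal(respiratory_fluxes(y, p, bolus, 3),
               respiratory_fluxes(y, p, cont0, 3))
  y0 <- stats::setNames(numeric(23), pbtk_states())
  expect_true(all(respiratory_fluxes(y0, p, bolus, 10) == 0))
  # active continuous source deposits EC*BR*60*FR into the entry regions
  cont <- continuous_scenario(EC = 100, BR = 2, duration = 6,
                              FR = c(upp = 0.3, tra = 0.1, alv = 0.2))
  d_on <- respiratory_fluxes(y0, p, cont, 1)
  expect_equal(d_on[["M_upp"]], 100 * 2 * 60 * 0.3)
  expect_equal(d_on[["M_alv"]], 100 * 2 * 60 * 0.2)
  expect_true(all(respiratory_fluxes(y0, p, cont, 6.01) == 0))  # cut-off
})

test_that("the assembled RHS conserves total mass at arbitrary states", {
  p <- default_parameters()
  bolus <- bolus_scenario(tra = 40, alv = 892)
  cont <- continuous_scenario(EC = 2e4, BR = 0.19, duration = 6,
                              FR = c(upp = 0.35, tra = 0.06, alv = 0.12))
  set.seed(7)
  for (i in 1:8) {
    y <- random_state()
    t <- runif(1, 0, 800)
    d <- pbtk_rhs(t, y, p, bolus)
    expect_lt(abs(sum(d)) / max(abs(d)), 1e-12)
    d2 <- pbtk_rhs(t, y, p, cont)
    src <- source_rate(cont, t) * sum(cont$FR)
    expect_lt(abs(sum(d2) - src) / max(abs(d2)), 1e-12)
  }
})

test_that("RHS boundary behavior: zero state, initial decline, bad input", {
  p <- default_parameters()
  sc <- bolus_scenario(tra = 40, alv = 892)
  y0 <- stats::setNames(numeric(23), pbtk_states())
  expect_true(all(pbtk_rhs(0, y0, p, sc) == 0))

  y <- initial_state(sc)
  d <- pbtk_rhs(1e-9, y, p, sc)
  expect_true(all(is.finite(d)))
  expect_lt(d[["M_tra"]], 0)  # mucociliary clearance dominates at onset

  y["M_art"] <- NaN
  expect_error(pbtk_rhs(0, y, p, sc), "non-finite state")
})

test_that("mass-balance audit tracks the integrated source", {
  expect_lt(mass_balance_audit(reference_run()), 1e-4)

  p <- default_parameters()
  zero <- run_simulation(p, bolus_scenario(), t_end = 10, dt = 1)
  expect_equal(mass_balance_audit(zero), 0)

  cont <- continuous_scenario(EC = 2e4, BR = 0.19, duration = 6,
                              FR = c(upp = 0.35, tra = 0.06, alv = 0.12))
  res <- run_simulation(p, cont, t_end = 48, dt = 0.25)
  expect_lt(mass_balance_audit(res),
            1e-4 * 2e4 * 0.19 * 60 * 6 * 0.53 / 1000)
  # final total equals the dosed mass minus nothing (sinks are states)
  dosed <- 2e4 * 0.19 * 60 * 6 * (0.35 + 0.06 + 0.12)
  expect_equal(sum(res$states[nrow(res$states), ]), dosed,
               tolerance = 1e-8)
})
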