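test_that("plasma curve validation and linear interpolation", {
  expect_error(plasma_curve(c(0, 0, 10), c(1, 2, 3)), "increasing")
  expect_error(plasma_curve(c(0, 10), c(-1, 2)), ">= 0")
  expect_error(plasma_curve(0, 1), "at least 2")

  pc <- plasma_curve(c(0, 10), c(0, 1000))
  expect_equal(interp_plasma(pc, 5), 500)
  expect_equal(interp_plasma(pc, c(0, 10)), c(0, 1000))  # exact at knots

  flat <- plasma_curve(c(0, 150), c(600, 600))
  expect_equal(interp_plasma(flat, 77), 600)

  tri <- plasma_curve(c(0, 10, 20), c(0, 2000, 600))
  expect_equal(interp_plasma(tri, 15), 1300)

  expect_error(interp_plasma(pc, 10.5), "span")
  expect_error(interp_plasma(pc, -0.1), "span")
})

test_that("effect site: steady state, constant-plasma closed form", {
  flat <- plasma_curve(c(0, 150), c(600, 600))
  for (ke in c(0.01, 0.1386, 5)) {
    es <- effect_site(flat, ke, eval_times = c(0, 33.3, 75, 150))
    expect_equal(es$concentrations, rep(600, 4))  # Ce = Cp fixed point
  }
  # ce0 = 0 under constant Cp: c(1 - exp(-ke t)), half the gap at t1/2e
  ke <- log(2) / 7
  es <- effect_site(flat, ke, ce0 = 0, eval_times = c(0, 7, 30))
  expect_equal(es$concentrations, 600 * (1 - exp(-ke * c(0, 7, 30))))
  expect_equal(es$concentrations[2], 300)
})

test_that("effect site matches the RK4 oracle on a ramp", {
  ramp <- plasma_curve(c(0, 10), c(0, 1000))
  ke <- log(2) / 5
  cf <- effect_site(ramp, ke, ce0 = 0, eval_times = 10)
  ora <- effect_site_ode_oracle(ramp, ke, ce0 = 0, eval_times = 10,
                                step = 1e-3)
  expect_lt(rel_err(cf$concentrations, ora$concentrations), 1e-6)
  # frozen value from the oracle (RK4, step 1e-3): Ce(10) = 458.98936
  expect_equal(cf$concentrations, 458.98936, tolerance = 1e-6)
})

test_that("oracle self-consistency: halving the step barely moves it", {
  withr_seed <- 424201
  set.seed(withr_seed)
  pc <- random_plasma_curve()
  ke <- 0.05
  a <- effect_site_ode_oracle(pc, ke, eval_times = c(60, 179), step = 2e-3)
  b <- effect_site_ode_oracle(pc, ke, eval_times = c(60, 179), step = 1e-3)
  expect_lt(max(rel_err(a$concentrations, b$concentrations)), 1e-8)
})

test_that("oracle equivalence property on random curves", {
  set.seed(99)
  for (i in 1:15) {
    pc <- random_plasma_curve()
    ke <- exp(runif(1, log(log(2) / 277), log(log(2) / 5)))
    tev <- sort(runif(20, 0, 180))
    cf <- effect_site(pc, ke, eval_times = tev)$concentrations
    ora <- effect_site_ode_oracle(pc, ke, eval_times = tev,
                                  step = 1e-3)$concentrations
    expect_lt(max(abs(cf - ora) / pmax(abs(ora), 1e-2 * max(ora))), 1e-5)
  }
})

test_that("effect site is continuous across knots and propagates exactly", {
  set.seed(7)
  pc <- random_plasma_curve()
  ke <- 0.03
  knots <- dopabuff:::effect_site_knots(pc, ke, pc$concentrations[1])
  # evaluating at the knots must reproduce the propagated knot values
  es <- effect_site(pc, ke, eval_times = pc$times)
  expect_equal(es$concentrations, knots)
  # approaching a knot from the left converges to the knot value
  inner <- pc$times[2]
  left <- effect_site(pc, ke, eval_times = inner - 1e-9)$concentrations
  expect_equal(left, knots[2], tolerance = 1e-6)
})

test_that("Ce converges to Cp as ke grows (equilibration limit)", {
  ramp <- plasma_curve(c(0, 10, 20), c(0, 1000, 1000))
  tev <- seq(0.5, 20, by = 0.5)
  cp <- interp_plasma(ramp, tev)
  gap <- sapply(c(1, 10, 100), function(ke)
    max(abs(effect_site(ramp, ke, eval_times = tev)$concentrations - cp)))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 11)  # m/ke lag bound: 100/ke
})

test_that("effect site rejects bad parameters", {
  pc <- plasma_curve(c(0, 10), c(0, 100))
  expect_error(effect_site(pc, ke = 0, eval_times = 5), "positive")
  expect_error(effect_site(pc, ke = 0.1, eval_times = 11), "span")
  expect_error(effect_site_ode_oracle(pc, 0.1, eval_times = 5, step = 0),
               "positive")
})

test_that("sigmoid Emax model: anchors and monotonicity", {
  p <- pd_params(e0 = 50, emax = 35, ec50 = 600, n = 3, ke = 0.1)
  expect_equal(hill_effect(0, p), 50)
  expect_equal(hill_effect(Inf, p), 85)
  expect_equal(hill_effect(1e12, p), 85, tolerance = 1e-6)
  # midpoint at ec50 for every Hill coefficient
  for (n in c(0.5, 1, 2, 8, 15)) {
    pn <- pd_params(e0 = 50, emax = 35, ec50 = 600, n = n, ke = 0.1)
    expect_equal(hill_effect(600, pn), 67.5)
  }
  # strictly increasing
  ce <- seq(0, 5000, by = 50)
  expect_true(all(diff(hill_effect(ce, p)) > 0))
  expect_error(hill_effect(-1, p), ">= 0")
  expect_error(pd_params(e0 = 50, emax = 35, ec50 = -5, n = 2, ke = 0.1))
})

test_that("t1/2e <-> ke conversion round-trips", {
  expect_equal(t_half_e(log(2)), 1)
  expect_equal(ke_from_t_half(5), log(2) / 5)
  expect_equal(ke_from_t_half(277), 0.002502, tolerance = 1e-3)
  x <- c(0.001, 0.1386, 2)
  expect_equal(ke_from_t_half(t_half_e(x)), x)
  expect_error(t_half_e(0))
  expect_error(ke_from_t_half(-3))
})

test_that("predict_time_effect composes the pieces", {
  p <- pd_params(e0 = 50, emax = 35, ec50 = 600, n = 3, ke = 0.05)
  zero <- plasma_curve(c(0, 100), c(0, 0))
  s <- predict_time_effect(zero, p, seq(0, 100, 10))
  expect_equal(s$values, rep(50, 11))
  expect_false(s$noisy)

  at_ec50 <- plasma_curve(c(0, 100), c(600, 600))
  s2 <- predict_time_effect(at_ec50, p, seq(0, 100, 10))
  expect_equal(s2$values, rep(67.5, 11))

  # severe equilibrates fast -> earlier peak than mild (shape property)
  su <- mean_setup()
  severe <- predict_time_effect(su$plasma, su$presets[[6]]$params,
                                su$frames)
  mild <- predict_time_effect(su$plasma, su$presets[[1]]$params,
                              su$frames)
  expect_lt(su$frames[which.max(severe$values)],
            su$frames[which.max(mild$values)])
  # severe rises then falls; mild still rising at infusion end
  expect_lt(which.max(severe$values), length(su$frames))
  expect_gt(which.max(mild$values), 0.9 * length(su$frames))
})
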