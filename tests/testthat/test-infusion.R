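test_that("regimen arithmetic matches the published worked example", {
  reg <- build_regimen(70, 65)
  expect_equal(reg$loading_dose_mg, 44.982)      # ~45 mg over 10 min
  expect_equal(reg$loading_duration_min, 10)
  expect_equal(reg$maintenance_rate_mg_min, 0.151305)  # ~0.15 mg/min
  expect_equal(total_dose(reg), 66.1647)         # ~66 mg over 150 min
  expect_equal(reg$total_duration_min, 150)
})

test_that("regimen validation", {
  expect_error(build_regimen(0, 65), "positive")
  expect_error(build_regimen(70, 140), "140")
  expect_error(build_regimen(70, 65, duration_scale = 0.5), ">= 1")
})

test_that("duration_scale stretches time and conserves total dose", {
  r1 <- build_regimen(70, 65)
  r2 <- build_regimen(70, 65, duration_scale = 2)
  expect_equal(r2$loading_duration_min, 20)
  expect_equal(r2$total_duration_min, 300)
  expect_equal(r2$loading_rate_mg_min, r1$loading_rate_mg_min / 2)
  expect_equal(r2$maintenance_rate_mg_min, r1$maintenance_rate_mg_min / 2)
  expect_identical(total_dose(r2), total_dose(r1))
})

test_that("pk scenarios validate their ordering", {
  expect_equal(pk_scenario("mean")$scale, 1)
  expect_gt(pk_scenario("high")$scale, 1)
  expect_lt(pk_scenario("low")$scale, 1)
  expect_error(pk_scenario("high", scale = 0.9), "> 1")
  expect_error(pk_scenario("low", scale = 1.2), "< 1")
  expect_error(pk_scenario("mean", scale = 2), "scale 1")
})

test_that("calibrated mean curve hits the printed plateau and peak", {
  su <- mean_setup()
  pc <- su$plasma
  plateau <- pc$concentrations[pc$times >= 100 & pc$times <= 150]
  expect_true(all(abs(plateau - 600) / 600 < 0.05))
  peak <- max(pc$concentrations)
  t_peak <- pc$times[which.max(pc$concentrations)]
  expect_gte(peak, 1500)
  expect_lte(peak, 3500)
  expect_lt(abs(t_peak - 10), 2)  # peak at end of loading
})

test_that("plateau decays monotonically from the peak", {
  su <- mean_setup()
  pc <- su$plasma
  i_peak <- which.max(pc$concentrations)
  i_end <- max(which(pc$times <= 150))
  seg <- pc$concentrations[i_peak:i_end]
  expect_true(all(diff(seg) < 0.05))  # tiny fp slack near the plateau
})

test_that("scenario curves are ordered pointwise and scale the mean", {
  su <- mean_setup()
  hi <- simulate_plasma(su$regimen, pk_scenario("high"), pk = su$pk)
  lo <- simulate_plasma(su$regimen, pk_scenario("low"), pk = su$pk)
  expect_true(all(hi$concentrations >= su$plasma$concentrations))
  expect_true(all(lo$concentrations <= su$plasma$concentrations))
  expect_equal(hi$concentrations, 1.5 * su$plasma$concentrations)
  expect_equal(lo$concentrations, 0.55 * su$plasma$concentrations)
})

test_that("zero infusion rates give an identically zero curve", {
  reg0 <- build_regimen(70, 65, loading_mg_per_kg = 0,
                        maintenance_coef = 0)
  pc <- simulate_plasma(reg0)
  expect_true(all(pc$concentrations == 0))
})

test_that("mass balance: with no elimination the body holds the dose", {
  su <- mean_setup()
  pk0 <- su$pk
  pk0$cl <- 0
  pc <- simulate_plasma(su$regimen, pk = pk0)
  expect_equal(sum(attr(pc, "amounts_mg")), total_dose(su$regimen),
               tolerance = 1e-8)
})

test_that("doubled-duration regimen stays within the peak band", {
  su <- mean_setup()
  reg2 <- build_regimen(70, 65, duration_scale = 2)
  pc2 <- simulate_plasma(reg2, pk = su$pk)
  expect_gte(max(pc2$concentrations), 1500)
  expect_lte(max(pc2$concentrations), 3500)
  # half the maintenance rate -> decays toward half the steady state,
  # approaching 300 ng/mL from above (loading overfills the smaller pool)
  late <- pc2$concentrations[pc2$times >= 200 & pc2$times <= 300]
  expect_true(all(diff(late) < 0))
  expect_gt(min(late), 300)
  expect_lt(max(late), 600)
})

test_that("calibration reports infeasibility instead of silently passing", {
  # an implausibly fast inter-compartmental clearance flattens the peak
  expect_error(calibrate_pk(70, 65, q_l_min = 50), "infeasible")
})
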