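test_that("objective is zero at truth on noiseless data, positive off it", {
  su <- mean_setup()
  p <- su$presets[[6]]$params
  obs <- predict_time_effect(su$plasma, p, su$frames)
  truth <- c(p$ke, p$ec50, p$n)
  expect_lt(pkpd_objective(truth, su$plasma, obs), 1e-18)
  for (fac in list(c(1.2, 1, 1), c(1, 0.8, 1), c(1, 1, 1.3)))
    expect_gt(pkpd_objective(truth * fac, su$plasma, obs), 1e-4)
  expect_error(pkpd_objective(c(-1, 600, 2), su$plasma, obs), "positive")
})

test_that("objective at truth on noisy data matches its expectation", {
  su <- mean_setup()
  p <- su$presets[[6]]$params
  obs <- predict_time_effect(su$plasma, p, su$frames)
  truth <- c(p$ke, p$ec50, p$n)
  expected <- sum((0.129 * obs$values)^2)  # sum of per-frame variances
  objs <- vapply(1:30, function(i)
    pkpd_objective(truth, su$plasma, add_noise(obs, 0.129, seed = i)),
    numeric(1))
  expect_lt(abs(mean(objs) - expected) / expected, 0.05)
})

test_that("zero-noise fit recovers a severe preset to high precision", {
  su <- mean_setup()
  p <- su$presets[[6]]$params
  obs <- predict_time_effect(su$plasma, p, su$frames)
  fit <- fit_pkpd(su$plasma, obs, seed = 1)
  expect_true(fit$converged)
  expect_lt(rel_err(fit$ke_hat, p$ke), 0.01)
  expect_lt(rel_err(fit$ec50_hat, p$ec50), 0.05)
  expect_lt(rel_err(fit$n_hat, p$n), 0.05)
})

test_that("fits are deterministic given the seed", {
  su <- mean_setup()
  p <- su$presets[[5]]$params
  obs <- add_noise(predict_time_effect(su$plasma, p, su$frames),
                   0.129, seed = 5)
  f1 <- fit_pkpd(su$plasma, obs, seed = 9)
  f2 <- fit_pkpd(su$plasma, obs, seed = 9)
  expect_identical(f1[c("ke_hat", "ec50_hat", "n_hat", "objective")],
                   f2[c("ke_hat", "ec50_hat", "n_hat", "objective")])
  expect_identical(f1$uncertainty, f2$uncertainty)
})

test_that("estimates respect the bounds even with truth near an edge", {
  su <- mean_setup()
  b <- pkpd_bounds()
  p <- pd_params(ec50 = 1500, n = 8, ke = b$ke[2] * 0.98)
  obs <- add_noise(predict_time_effect(su$plasma, p, su$frames),
                   0.129, seed = 3)
  fit <- fit_pkpd(su$plasma, obs, seed = 3)
  expect_gte(fit$ke_hat, b$ke[1]); expect_lte(fit$ke_hat, b$ke[2])
  expect_gte(fit$ec50_hat, b$ec50[1]); expect_lte(fit$ec50_hat, b$ec50[2])
  expect_gte(fit$n_hat, b$n[1]); expect_lte(fit$n_hat, b$n[2])
})

test_that("pure noise around baseline is flagged non-identifiable", {
  su <- mean_setup()
  flat <- time_effect_series(su$frames, rep(50, length(su$frames)),
                             e0 = 50)
  noisy <- add_noise(flat, 0.129, seed = 21)
  fit <- fit_pkpd(su$plasma, noisy, seed = 21)
  expect_false(fit$converged)
  expect_false(fit$diagnostics$identifiable)
  # exactly constant series is degenerate too
  fit0 <- fit_pkpd(su$plasma, flat, seed = 1)
  expect_false(fit0$converged)
})

test_that("uncertainty percentiles bracket the point estimate sanely", {
  su <- mean_setup()
  p <- su$presets[[6]]$params
  obs <- add_noise(predict_time_effect(su$plasma, p, su$frames),
                   0.05, seed = 13)
  fit <- fit_pkpd(su$plasma, obs, seed = 13)
  u <- fit$uncertainty
  expect_true(all(u["5%", ] <= u["50%", ] & u["50%", ] <= u["95%", ]))
  expect_gte(fit$ke_hat, u["5%", "ke"] * 0.5)
  expect_lte(fit$ke_hat, u["95%", "ke"] * 2)
})

test_that("fit input validation", {
  su <- mean_setup()
  p <- su$presets[[6]]$params
  obs <- predict_time_effect(su$plasma, p, su$frames)
  expect_error(fit_pkpd(su$plasma, obs, bounds = list(ke = c(1, 0.1),
               ec50 = c(50, 5000), n = c(0.5, 15))), "bounds")
  short <- time_effect_series(1:3, c(50, 51, 52))
  expect_error(fit_pkpd(su$plasma, short), "4 frames")
  late <- time_effect_series(c(100, 400), c(50, 60))
  expect_error(pkpd_objective(c(0.1, 600, 2), su$plasma, late), "span")
})
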