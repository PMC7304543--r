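cfg <- imaging_config()
tab_model <- gbm_shapes("table")

test_that("ratio inversion is the inverse of the forward ratio", {
  for (rh0 in c(0.5, 2, 8)) {
    target <- f_of_rho_hat(rh0, tab_model)
    rh <- solve_rho_hat(target, tab_model, cfg)
    expect_equal(as.numeric(rh), rh0, tolerance = 1e-8)
  }
  # linear shapes: the derived f(1) ~ 0.5277 inverts back to 1
  rh <- solve_rho_hat(0.5276514271, gbm_shapes("linear"), cfg)
  expect_equal(as.numeric(rh), 1, tolerance = 1e-5)
})

test_that("unattainable width ratios raise an identifiability error", {
  err <- tryCatch(solve_rho_hat(100, tab_model, cfg), error = function(e) e)
  expect_s3_class(err, "gbmwave_identifiability_error")
  expect_match(conditionMessage(err), "attainable range")
  expect_error(solve_rho_hat(-1, tab_model, cfg), "positive")
})

test_that("detectability radius satisfies the point-source identities", {
  for (D in c(0.2, 0.4)) {
    for (rho in c(0.22, 0.3)) {
      r1 <- exponential_phase_radius(D, rho, cfg$a1, cfg)
      r2 <- exponential_phase_radius(D, rho, cfg$a2, cfg)
      expect_gt(r2, r1)  # lower threshold detected farther out
      # algebraic identity: R2^2 - R1^2 = 4 D t* log(a1/a2)
      expect_equal(r2^2 - r1^2, 4 * D * cfg$t_star * log(cfg$a1 / cfg$a2),
                   tolerance = 1e-10)
    }
  }
  # threshold exactly at the detectability limit gives radius 0
  D <- 0.2; rho <- 0.1
  a_crit <- cfg$p0 * exp(rho * cfg$t_star) / (4 * pi * D * cfg$t_star)^1.5
  expect_equal(exponential_phase_radius(D, rho, a_crit, cfg), 0,
               tolerance = 1e-6)
  expect_error(exponential_phase_radius(D, rho, a_crit * 1.01, cfg),
               "undetectable")
})

test_that("segmentation volumes map to equivalent-sphere radii", {
  expect_equal(volumes_to_radii(4 * pi / 3, 0, 0),
               c(R0 = 1, R1 = 1, R2 = 1))
  expect_equal(volumes_to_radii(0, 0, 0), c(R0 = 0, R1 = 0, R2 = 0))
  expect_equal(volumes_to_radii(4 * pi / 3, 4 * pi / 3 * 7, 4 * pi / 3 * 19),
               c(R0 = 1, R1 = 2, R2 = 3))
  expect_error(volumes_to_radii(-1, 0, 0), "non-negative")
})

test_that("two-scan estimation inverts forward-modelled patients exactly", {
  for (tr in list(c(D = 0.3, rho = 0.2, k = 0.06),
                  c(D = 0.1, rho = 0.18, k = 0.15),
                  c(D = 0.8, rho = 0.25, k = 0.05))) {
    obs <- synthetic_patient(tr[["D"]], tr[["rho"]], tr[["k"]], age = 300,
                             config = cfg, model = tab_model)
    fit <- estimate_two_scan(obs, cfg, tab_model)
    expect_equal(coef(fit), tr, tolerance = 1e-6)
    expect_lt(max(abs(residuals(fit))), 1e-7)
  }
})

test_that("two-scan back-substitution obeys its scaling laws", {
  obs <- synthetic_patient(0.3, 0.2, 0.06, age = 300, config = cfg,
                           model = tab_model)
  fit1 <- estimate_two_scan(obs, cfg, tab_model)
  obs2 <- patient_observation(obs$R0, obs$R1, obs$R2, V = 2 * obs$V,
                              velocity_source = "R1")
  fit2 <- estimate_two_scan(obs2, cfg, tab_model)
  expect_equal(fit2$rho_hat, fit1$rho_hat, tolerance = 1e-10)  # V-independent
  expect_equal(fit2$k, 2 * fit1$k, tolerance = 1e-10)
  expect_equal(fit2$rho, 2 * fit1$rho, tolerance = 1e-10)
  expect_equal(fit2$D, (2 * obs$V / 2)^2 / fit2$rho, tolerance = 1e-10)
})

test_that("two-scan estimates are unit-consistent (cm vs mm)", {
  obs_mm <- synthetic_patient(0.3, 0.2, 0.06, age = 300, config = cfg,
                              model = tab_model)
  fit_mm <- estimate_two_scan(obs_mm, cfg, tab_model)
  obs_cm <- patient_observation(obs_mm$R0 / 10, obs_mm$R1 / 10,
                                obs_mm$R2 / 10, V = obs_mm$V / 10,
                                velocity_source = "R1")
  fit_cm <- estimate_two_scan(obs_cm, cfg, tab_model)
  expect_equal(fit_cm$rho, fit_mm$rho, tolerance = 1e-9)
  expect_equal(fit_cm$k, fit_mm$k, tolerance = 1e-9)
  expect_equal(fit_cm$D * 100, fit_mm$D, tolerance = 1e-9)
})

test_that("single-scan round trip is exact on the consistent manifold", {
  tr <- consistent_truth(0.3, 0.2, 0.06, age = 300, config = cfg,
                         model = tab_model)
  obs <- synthetic_patient(tr$D, tr$rho, tr$k, age = tr$age, config = cfg,
                           model = tab_model)
  obs$V <- NULL
  fit <- estimate_single_scan(obs, cfg, tab_model)
  expect_equal(fit$D, tr$D, tolerance = 1e-4)
  expect_equal(fit$rho, tr$rho, tolerance = 1e-4)
  expect_equal(fit$k, tr$k, tolerance = 1e-4)
})

test_that("single-scan and two-scan protocols agree at the implied speed", {
  obs1 <- patient_observation(14.87, 20.73, 27.77)
  fit1 <- estimate_single_scan(obs1, cfg, tab_model)
  obs2 <- patient_observation(14.87, 20.73, 27.77, V = fit1$c,
                              velocity_source = "R1")
  fit2 <- estimate_two_scan(obs2, cfg, tab_model)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-6)
})

test_that("every estimate satisfies the output contract", {
  fits <- list(
    gbm_fit(R0 = 14.87, R1 = 20.73, R2 = 27.77, config = cfg,
            model = tab_model),
    gbm_fit(R0 = 10, R1 = 14, R2 = 20, V = 0.4, config = cfg,
            model = tab_model))
  for (fit in fits) {
    expect_equal(fit$rho_hat, fit$rho / fit$k, tolerance = 1e-9)
    expect_equal(fit$c, 2 * sqrt(fit$rho * fit$D), tolerance = 1e-9)
    expect_true(all(c(fit$D, fit$rho, fit$k) > 0))
  }
})

test_that("observation validation enforces the radius ordering", {
  expect_error(patient_observation(5, 4, 6), "R0 < R1 < R2")
  expect_error(patient_observation(0, 4, 6), "R0 < R1 < R2")
  expect_error(patient_observation(1, 4, 4), "R0 < R1 < R2")
  expect_error(patient_observation(1, 4, 6, V = -1), "positive")
})

test_that("fit methods expose the expected interfaces", {
  fit <- gbm_fit(R0 = 14.87, R1 = 20.73, R2 = 27.77, config = cfg,
                 model = tab_model)
  expect_named(coef(fit), c("D", "rho", "k"))
  expect_output(print(fit), "single-scan")
  expect_output(print(summary(fit)), "residuals")
  expect_named(residuals(fit),
               c("l1_minus_L1", "l2_minus_L2", "third_equation"))
  # width equations are satisfied by construction in the single-scan protocol
  expect_lt(max(abs(residuals(fit)[1:2])), 1e-6)
  pred <- predict(fit, times = c(60, 100, 200))
  expect_true(all(diff(pred$R1) > 0))
  expect_true(all(pred$R2 > pred$R1, na.rm = TRUE))
  # prediction at the estimated age reproduces the measured radii
  at_age <- predict(fit, times = fit$tumor_age)
  expect_equal(c(at_age$R0, at_age$R1, at_age$R2),
               c(14.87, 20.73, 27.77), tolerance = 1e-3)
  sim <- simulate(fit, nsim = 2, seed = 7, noise_sd = 0.3)
  expect_equal(nrow(sim), 2)
  expect_true(all(c("R0_mm", "R1_mm", "R2_mm") %in% names(sim)))
})
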