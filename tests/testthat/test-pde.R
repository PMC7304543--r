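test_that("zero initial data stays identically zero", {
  sim <- simulate_tumor_pde(rho_hat = 1, domain_length = 20, n_cells = 200,
                            t_end = 2, n_save = 5,
                            initial = list(amplitude = 0, width = 1))
  expect_equal(max(abs(sim$p)), 0)
  expect_equal(max(abs(sim$q)), 0)
})

test_that("with death switched off the solver reproduces the Fisher-KPP speed", {
  fisher <- list(g = function(w) w, delta = function(w) 0 * w)
  sim <- test_pde(1, model = fisher)
  expect_equal(max(sim$q), 0)               # no quiescence without death
  mw <- measure_wave(sim)
  expect_equal(mw$speed, 2, tolerance = 0.05)
})

test_that("discrete conservation: d/dt sum(p+q) equals the birth integral", {
  sim <- simulate_tumor_pde(rho_hat = 1.5, domain_length = 40, n_cells = 400,
                            t_end = 10, n_save = 5)
  r <- gbmwave:::as_responses(gbm_shapes("table"))
  y <- c(sim$p[5, ], sim$q[5, ])
  dy <- sim$rhs(0, y, NULL)[[1]]
  n <- length(sim$x)
  w <- pmin(pmax(1 - (sim$p[5, ] + sim$q[5, ]), 0), 1)
  birth <- 1.5 * r$g(w) * sim$p[5, ]
  # fluxes telescope: total rate of change must equal total birth exactly
  expect_equal(sum(dy) * sim$dx, sum(birth) * sim$dx, tolerance = 1e-12)
})

test_that("solutions remain bounded and quiescence accumulates monotonically", {
  sim <- test_pde(2)
  expect_gte(min(sim$p), -1e-6)
  expect_gte(min(sim$q), -1e-6)
  expect_lte(max(sim$p + sim$q), 1 + 1e-6)
  # q is a sink: non-decreasing in time at every grid point
  expect_true(all(diff(sim$q) >= -1e-9))
  # the growth-factor identity w = 1 - p - q holds by construction
  w <- 1 - sim$p - sim$q
  expect_equal(max(abs(sim$p + sim$q + w - 1)), 0)
})

test_that("late-time profiles translate at constant speed without deformation", {
  sim <- test_pde(1)
  mw <- measure_wave(sim)
  nt <- length(sim$times)
  i1 <- nt - 4; i2 <- nt
  dt <- sim$times[i2] - sim$times[i1]
  shifted <- approx(sim$x + mw$speed * dt, sim$p[i1, ], xout = sim$x)$y
  interior <- !is.na(shifted) & sim$x > 10 &
    sim$x < max(mw$front$x, na.rm = TRUE) + 5
  expect_lt(max(abs(sim$p[i2, interior] - shifted[interior])) / mw$p_max,
            0.02)
})

test_that("halving the grid spacing changes the measured speed by under 1%", {
  sim1 <- simulate_tumor_pde(rho_hat = 1, domain_length = 60, n_cells = 600)
  sim2 <- simulate_tumor_pde(rho_hat = 1, domain_length = 60, n_cells = 1200)
  s1 <- measure_wave(sim1)$speed
  s2 <- measure_wave(sim2)$speed
  expect_lt(abs(s1 - s2) / s2, 0.01)
})

test_that("fronts reaching the boundary raise a measurement error", {
  sim <- simulate_tumor_pde(rho_hat = 1, domain_length = 30, n_cells = 300,
                            t_end = 30)
  expect_error(measure_wave(sim), "boundary")
  expect_error(simulate_tumor_pde(rho_hat = 1, n_cells = 50), "at least")
})

test_that("dimensional runs report their scales", {
  sim <- simulate_tumor_pde(D = 0.3, rho = 0.2, k = 0.1, domain_length = 40,
                            n_cells = 400, t_end = 10, n_save = 5)
  expect_equal(sim$rho_hat, 2)
  expect_equal(sim$length_scale_mm, sqrt(0.3 / 0.1))
  expect_equal(sim$time_scale_days, 10)
})
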