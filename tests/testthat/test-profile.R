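linear <- gbm_shapes("linear")

test_that("numerical profile matches the closed form for linear responses", {
  for (rh in c(0.5, 1, 3)) {
    prof <- wave_profile(rh, linear)
    w <- seq(prof$w_star + 0.01, 0.999, length.out = 200)
    expect_lt(max(abs(prof$p(w) - p_linear(w, rh))), 1e-8)
    # peak location from delta = rho_hat * g: (1 - w) = rho_hat * w
    expect_equal(prof$w_peak, 1 / (1 + rh), tolerance = 1e-10)
    expect_equal(prof$p_max, p_linear(1 / (1 + rh), rh), tolerance = 1e-8)
    # plateau from the bisection oracle on the closed form
    w_star_oracle <- solve_p_linear(0, rh, c(1e-12, 1 / (1 + rh)))
    expect_equal(prof$w_star, w_star_oracle, tolerance = 1e-8)
  }
})

test_that("profile boundary behaviour and input validation", {
  prof <- wave_profile(1, linear)
  expect_equal(prof$p(1), 0)
  expect_gt(prof$p((prof$w_star + prof$w_peak) / 2), 0)
  expect_error(wave_profile(-1), "positive")
  expect_error(wave_profile(0), "positive")
})

test_that("threshold crossings agree with bisection on the closed form", {
  prof <- wave_profile(1, linear)
  cr9 <- threshold_crossings(prof, 0.9)
  p_max <- p_linear(0.5, 1)
  expect_equal(cr9[["w_in"]],
               solve_p_linear(0.9 * p_max, 1, c(0.21, 0.5)), tolerance = 1e-9)
  expect_equal(cr9[["w_out"]],
               solve_p_linear(0.9 * p_max, 1, c(0.5, 0.999)), tolerance = 1e-9)
  cr1 <- threshold_crossings(prof, 0.1)
  expect_equal(cr1[["w_out"]],
               solve_p_linear(0.1 * p_max, 1, c(0.5, 0.9999)), tolerance = 1e-9)
  # near the peak both crossings collapse onto w_peak
  cr <- threshold_crossings(prof, 0.99999)
  expect_equal(unname(cr), c(0.5, 0.5), tolerance = 1e-2)
  expect_error(threshold_crossings(prof, 1), "strictly")
  expect_error(threshold_crossings(prof, 0), "strictly")
})

test_that("width integrals match a fine trapezoid oracle", {
  prof <- wave_profile(1, linear)
  met <- width_integrals(prof, 0.9, 0.1)
  I1_oracle <- trapezoid_width_linear(met$w_a1_in, met$w_a1_out, 1)
  I2_oracle <- trapezoid_width_linear(met$w_a1_out, met$w_a2_out, 1)
  expect_equal(met$I1, I1_oracle, tolerance = 1e-6)
  expect_equal(met$I2, I2_oracle, tolerance = 1e-6)
  expect_equal(met$f_ratio, met$I1 / met$I2)
  expect_true(met$w_a1_in < prof$w_peak && prof$w_peak < met$w_a1_out &&
                met$w_a1_out < met$w_a2_out && met$w_a2_out < 1)
  expect_error(width_integrals(prof, 0.1, 0.9), "a2 < a1")
})

test_that("width integrals respond monotonically to the thresholds", {
  prof <- wave_profile(1, gbm_shapes("table"))
  m_ref <- width_integrals(prof, 0.9, 0.1)
  expect_gt(m_ref$I1, 0)
  expect_gt(m_ref$I2, 0)
  # I1 shrinks as a1 -> 1; I2 grows as a2 -> 0
  expect_lt(width_integrals(prof, 0.99, 0.1)$I1, m_ref$I1)
  expect_lt(width_integrals(prof, 0.999, 0.1)$I1,
            width_integrals(prof, 0.99, 0.1)$I1)
  expect_gt(width_integrals(prof, 0.9, 0.02)$I2, m_ref$I2)
})

test_that("profile exists across shapes and rho_hat decades", {
  for (m in list(gbm_shapes("linear"), gbm_shapes("sigmoid"),
                 gbm_shapes("concave-up"), gbm_shapes("concave-down"),
                 gbm_shapes("table"))) {
    for (rh in c(0.1, 1, 10)) {
      prof <- wave_profile(rh, m)
      expect_true(prof$w_star >= 0 && prof$w_star < prof$w_peak)
      expect_true(prof$w_peak < 1)
      expect_gt(prof$p_max, 0)
    }
  }
})

test_that("identifiability ratio is monotone and scale-free", {
  grid <- c(0.5, 1.5, 3, 5)
  for (m in list(gbm_shapes("table"), gbm_shapes("linear"))) {
    fv <- f_of_rho_hat(grid, m)
    expect_true(all(diff(fv) > 0))
  }
  # f depends only on rho_hat and the thresholds, not on D and k separately
  expect_equal(f_of_rho_hat(2, linear), f_of_rho_hat(2, linear))
})

test_that("nondimensional wave speed follows 2*sqrt(rho_hat)", {
  expect_equal(wave_speed(1), 2)
  expect_equal(wave_speed(4), 4)
  expect_error(wave_speed(0), "positive")
  # dimensional arithmetic for a published patient parameterization
  expect_equal(2 * sqrt(0.2102 * 0.2852), 0.4897, tolerance = 1e-4)
})

test_that("profile table export is well-formed", {
  prof <- wave_profile(1, linear)
  path <- tempfile(fileext = ".csv")
  export_profile(prof, path)
  tab <- read.csv(path)
  expect_named(tab, c("w", "p", "z"))
  expect_true(all(tab$p > 0))
  expect_true(all(diff(tab$w) > 0))
  unlink(path)
})
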