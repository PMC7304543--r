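cfg <- imaging_config()

test_that("noise-free generation is a deterministic function of the truth", {
  o1 <- synthetic_patient(0.3, 0.2, 0.06, age = 300, config = cfg)
  o2 <- synthetic_patient(0.3, 0.2, 0.06, age = 300, config = cfg)
  expect_identical(unclass(o1)[c("R0", "R1", "R2", "V")],
                   unclass(o2)[c("R0", "R1", "R2", "V")])
  tr <- attr(o1, "truth")
  expect_equal(tr$rho_hat, 0.2 / 0.06)
  expect_equal(o1$V, 2 * sqrt(0.2 * 0.3))
  expect_equal(o1$R2 - o1$R1, tr$l2)
  expect_equal(o1$R1 - o1$R0, tr$l1)
})

test_that("a recorded seed reproduces noisy draws exactly", {
  a <- synthetic_patient(0.3, 0.2, 0.06, age = 300, noise_sd = 0.5, seed = 11)
  b <- synthetic_patient(0.3, 0.2, 0.06, age = 300, noise_sd = 0.5, seed = 11)
  c <- synthetic_patient(0.3, 0.2, 0.06, age = 300, noise_sd = 0.5, seed = 12)
  expect_identical(c(a$R0, a$R1, a$R2), c(b$R0, b$R1, b$R2))
  expect_false(identical(c(a$R0, a$R1, a$R2), c(c$R0, c$R1, c$R2)))
  # noise-free radii differ from the noisy ones
  nf <- synthetic_patient(0.3, 0.2, 0.06, age = 300)
  expect_false(identical(a$R1, nf$R1))
})

test_that("cohort generation is reproducible and round-trips via two scans", {
  coh1 <- synthetic_cohort(4, seed = 5)
  coh2 <- synthetic_cohort(4, seed = 5)
  expect_identical(coh1$patients, coh2$patients)
  est <- estimate_cohort(coh1$patients, config = cfg)
  expect_true(all(est$status == "ok"))
  expect_equal(est$D_mm2_per_day, coh1$truth$D, tolerance = 1e-6)
  expect_equal(est$rho_per_day, coh1$truth$rho, tolerance = 1e-6)
  expect_equal(est$k_per_day, coh1$truth$k, tolerance = 1e-6)
})

test_that("generator input validation", {
  expect_error(synthetic_patient(0.3, 0.2, 0.06, age = 30, config = cfg),
               "t_star")
  expect_error(synthetic_patient(-0.3, 0.2, 0.06, age = 300), "D > 0")
})

test_that("global RNG state is untouched by seeded generation", {
  set.seed(999)
  before <- .Random.seed
  invisible(synthetic_patient(0.3, 0.2, 0.06, age = 300, noise_sd = 0.5,
                              seed = 3))
  expect_identical(.Random.seed, before)
})
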