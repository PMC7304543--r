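test_that("beta-CDF responses hit their endpoint and symmetry values", {
  m_unif <- gbm_model(1, 1, 1, 1)
  expect_identical(growth_response(m_unif, 0.5), 0.5)     # uniform CDF
  expect_identical(death_response(m_unif, 0.3), 0.7)      # 1 - w
  m_sig <- gbm_model(2, 2, 2, 2)
  expect_equal(growth_response(m_sig, 0.5), 0.5)          # symmetric median
  expect_equal(death_response(m_sig, 0.5), 0.5)
  for (m in list(m_unif, m_sig, gbm_model(3.7, 0.4, 1.2, 5))) {
    expect_identical(growth_response(m, c(0, 1)), c(0, 1))
    expect_identical(death_response(m, c(0, 1)), c(1, 0))
  }
})

test_that("responses are monotone for arbitrary positive shapes", {
  set.seed(41)
  w <- seq(0, 1, length.out = 301)
  for (i in 1:20) {
    shp <- exp(runif(4, log(0.2), log(6)))
    m <- gbm_model(shp[1], shp[2], shp[3], shp[4])
    expect_true(all(diff(growth_response(m, w)) >= 0))
    expect_true(all(diff(death_response(m, w)) <= 0))
  }
})

test_that("domain and constructor validation", {
  m <- gbm_model()
  expect_error(growth_response(m, -0.1), "0, 1")
  expect_error(death_response(m, 1.5), "0, 1")
  expect_error(gbm_model(0, 1, 1, 1), "positive")
  expect_error(gbm_model(1, 1, 1, 1, rho = -1), "rho")
  expect_error(gbm_model(1, 1, 1, 1, k = 0), "k")
})

test_that("constraint report passes for beta models and flags violations", {
  for (nm in c("linear", "sigmoid", "table")) {
    rep <- validate_constraints(gbm_shapes(nm))
    expect_true(all(rep$pass), info = nm)
  }
  rep <- validate_constraints(gbm_model(2, 2, 2, 2), n_grid = 501)
  expect_true(all(rep$pass))
  # injected violation: growth response with g(0) = 0.1
  bad <- list(g = function(w) 0.1 + 0.9 * w, delta = function(w) 1 - w)
  rep_bad <- validate_constraints(bad)
  expect_false(rep_bad$pass[rep_bad$condition == "g(0) = 0"])
  expect_false(rep_bad$pass[rep_bad$condition == "k*delta(0) > rho*g(0)"])
  expect_true(rep_bad$pass[rep_bad$condition == "g non-decreasing"])
})
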