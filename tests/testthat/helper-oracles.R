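# Independent oracles used across the test files.

# Closed-form wave profile for linear responses g(w) = w, delta(w) = 1 - w:
# integrating dp/dw = (1 - w) / (rho_hat * w) - 1 from p(1) = 0 gives
#   p(w) = (1 - w) * (1 + 1/rho_hat) + log(w) / rho_hat.
p_linear <- function(w, rho_hat) {
  (1 - w) * (1 + 1 / rho_hat) + log(w) / rho_hat
}

# Bisection oracle: solve p_linear(w) = target on a given interval.
solve_p_linear <- function(target, rho_hat, interval) {
  uniroot(function(w) p_linear(w, rho_hat) - target, interval,
          tol = 1e-14)$root
}

# Fine-grid trapezoid oracle for the width integrand 1/(rho_hat * p * g)
# on the closed-form linear profile.
trapezoid_width_linear <- function(lower, upper, rho_hat, n = 200001) {
  w <- seq(lower, upper, length.out = n)
  y <- 1 / (rho_hat * p_linear(w, rho_hat) * w)
  sum((y[-1] + y[-n]) / 2) * (w[2] - w[1])
}

# Published six-patient cohort: radii (mm) and the reported parameters.
table1 <- data.frame(
  patient_id = as.character(1:6),
  R0_mm = c(14.87, 20.48, 6.61, 22.87, 8.17, 8.29),
  R1_mm = c(20.73, 26.34, 10.91, 26.96, 14.20, 15.83),
  R2_mm = c(27.77, 38.24, 15.24, 37.03, 25.10, 20.35),
  D = c(0.2852, 1.2791, 0.0825, 0.9825, 0.9769, 0.0687),
  rho = c(0.2102, 0.2624, 0.1736, 0.2590, 0.2520, 0.1652),
  k = c(0.0602, 0.3537, 0.0327, 0.7819, 0.2260, 0.0106),
  stringsAsFactors = FALSE)

# Shared small PDE settings for test runs (coarser than the defaults, big
# enough for the measured tolerances used in the tests).
test_pde <- function(rho_hat, model = gbm_shapes("table"), ...) {
  simulate_tumor_pde(rho_hat = rho_hat, model = model,
                     domain_length = 90, n_cells = 900, ...)
}
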