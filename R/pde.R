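# Method-of-lines solver for the full 1-D cross-diffusion system
#
#   dp/dt = d/dx[ (p/(p+q)) d(p+q)/dx ] + rho_hat g(w) p - delta(w) p
#   dq/dt = d/dx[ (q/(p+q)) d(p+q)/dx ] + delta(w) p,    w = 1 - p - q,
#
# in nondimensional form (length scale sqrt(D/k), time scale 1/k). Fluxes are
# conservative: at each cell face the total-density gradient is multiplied by
# the face-interpolated population fractions, so that summed over the domain
# the diffusion terms telescope to zero and d/dt sum(p+q) equals the discrete
# birth integral exactly.

#' Simulate the full cross-diffusion tumor growth system
#'
#' Solves the nondimensional two-population system by the method of lines on
#' a uniform grid with no-flux boundaries. Time integration is classic RK4
#' (via `deSolve::ode`) at a fixed CFL-safe step: the degenerate
#' cross-diffusion fraction is non-smooth at the vacuum edge, which defeats
#' the error estimators of adaptive and implicit integrators, while the
#' problem itself is no stiffer than the diffusive CFL limit. Accuracy is
#' controlled by the grid (see the grid-convergence tests), not by a step
#' tolerance. The cross-diffusion flux of each population at a cell
#' face is the total-density gradient times that population's face-averaged
#' share of the total density, regularized as `p / (p + q + eps)` to handle
#' the vacuum ahead of the front. Dimensional parameters may be supplied
#' instead of `rho_hat`; the solver then rescales internally and reports
#' fields in mm and days.
#'
#' @param rho_hat dimensionless `rho / k`; alternatively give `D`, `rho`, `k`.
#' @param model a [gbm_model()] (or list of callables `g`, `delta`).
#' @param D,rho,k optional dimensional parameters (mm^2/day, /day, /day).
#' @param domain_length nondimensional domain length.
#' @param n_cells number of grid cells (>= 100).
#' @param t_end final nondimensional time; default lets the front cross about
#'   70% of the domain at speed `2 sqrt(rho_hat)`.
#' @param n_save number of saved time slices.
#' @param initial list with `amplitude` and `width` of the Gaussian seed
#'   `p(x, 0) = amplitude * exp(-(x / width)^2)` at the left boundary;
#'   `q(x, 0) = 0`. `amplitude = 0` gives the identically-zero solution.
#' @param dt time step; defaults to a CFL-safe fraction of the diffusive
#'   limit, `0.3 * dx^2`.
#' @param eps vacuum regularization of the population fractions.
#' @param negativity_tol solution values below `-negativity_tol` raise an
#'   error (positivity is conjectured, not guaranteed, for cross diffusion;
#'   violations are reported, never clipped).
#' @return an object of class `gbm_simulation`: list with `x` (cell centers),
#'   `times`, matrices `p` and `q` (time by space), `rho_hat`, `dx`, and — for
#'   dimensional input — the scales `length_scale_mm` and `time_scale_days`.
#' @seealso [measure_wave()] for front speed and width measurements.
#' @export
simulate_tumor_pde <- function(rho_hat = NULL, model = gbm_shapes("table"),
                               D = NULL, rho = NULL, k = NULL,
                               domain_length = 200, n_cells = 2000,
                               t_end = NULL, n_save = 81,
                               initial = list(amplitude = 0.05, width = 1),
                               dt = NULL, eps = 1e-12,
                               negativity_tol = 1e-6) {
  dimensional <- !is.null(D)
  if (dimensional) {
    stopifnot(D > 0, rho > 0, k > 0)
    rho_hat <- rho / k
  }
  if (is.null(rho_hat) || rho_hat <= 0)
    stop("rho_hat (or D, rho, k) must be given and positive", call. = FALSE)
  if (n_cells < 100) stop("n_cells must be at least 100", call. = FALSE)
  if (is.null(t_end)) t_end <- 0.7 * domain_length / wave_speed(rho_hat)
  dx <- domain_length / n_cells
  x <- (seq_len(n_cells) - 0.5) * dx
  p0 <- initial$amplitude * exp(-(x / initial$width)^2)
  y0 <- c(p0, numeric(n_cells))
  times <- seq(0, t_end, length.out = n_save)
  if (is.null(dt)) dt <- 0.3 * dx^2
  rhs <- .make_pde_rhs(n_cells, dx, rho_hat, model, eps)
  r <- as_responses(model)
  # responses tabulated on a dense uniform w-grid for the compiled kernel
  w_tab <- seq(0, 1, length.out = 8193)
  t_save <- t_end / (n_save - 1)
  steps_per_save <- max(1L, ceiling(t_save / dt))
  sol <- .pde_integrate(y0, dx, t_save / steps_per_save,
                        n_save, steps_per_save, rho_hat,
                        r$g(w_tab), r$delta(w_tab), eps)
  p <- sol[, seq_len(n_cells), drop = FALSE]
  q <- sol[, n_cells + seq_len(n_cells), drop = FALSE]
  if (min(p) < -negativity_tol || min(q) < -negativity_tol)
    stop(sprintf(
      "solver error: negative densities beyond tolerance (min p = %.3g, min q = %.3g)",
      min(p), min(q)), call. = FALSE)
  out <- structure(
    list(x = x, times = times, p = p, q = q, rho_hat = rho_hat, dx = dx,
         rhs = rhs, dimensional = dimensional),
    class = "gbm_simulation")
  if (dimensional) {
    out$length_scale_mm <- sqrt(D / k)
    out$time_scale_days <- 1 / k
  }
  out
}

# Reference R implementation of the semi-discrete right-hand side (same
# discretization as the compiled kernel, exact responses); kept on the
# result object so the discrete conservation identity can be audited.
.make_pde_rhs <- function(n, dx, rho_hat, model, eps) {
  r <- as_responses(model)
  g <- r$g; delta <- r$delta
  function(t, y, parms) {
    p <- y[seq_len(n)]
    q <- y[n + seq_len(n)]
    u <- p + q
    grad <- diff(u) / dx                      # at interior faces
    denom <- u[-n] + u[-1] + eps
    Fp <- (p[-n] + p[-1]) / denom * grad
    Fq <- (q[-n] + q[-1]) / denom * grad
    diff_p <- (c(Fp, 0) - c(0, Fp)) / dx      # no-flux boundaries
    diff_q <- (c(Fq, 0) - c(0, Fq)) / dx
    w <- pmin(pmax(1 - u, 0), 1)
    birth <- rho_hat * g(w) * p
    death <- delta(w) * p
    list(c(diff_p + birth - death, diff_q + death))
  }
}

#' @export
print.gbm_simulation <- function(x, ...) {
  cat(sprintf("Cross-diffusion simulation: rho_hat = %g, %d cells, t in [0, %g]\n",
              x$rho_hat, length(x$x), max(x$times)))
  cat(sprintf("  final max p = %.4g, max p+q = %.4g, min density = %.3g\n",
              max(x$p[nrow(x$p), ]), max(x$p + x$q), min(x$p, x$q)))
  invisible(x)
}

#' @export
plot.gbm_simulation <- function(x, slices = 5, ...) {
  idx <- unique(round(seq(1, length(x$times), length.out = slices)))
  matplot(x$x, t(x$p[idx, , drop = FALSE]), type = "l", lty = 1,
          xlab = "x (nondimensional)", ylab = "p", ...)
  invisible(x)
}

#' Measure wave diagnostics from a simulation
#'
#' Tracks the front (outermost crossing of `p + q` through `level`, linearly
#' interpolated) through time, fits the front speed by least squares over
#' `fit_window` (a fraction of the simulated time span), and measures the
#' peak proliferating density and the rim/edema widths from the final
#' profile: `L1` is the width of the region with `p >= a1 * pmax`, `L2` runs
#' from the outer `a1 * pmax` crossing to the outer `a2 * pmax` crossing.
#'
#' @param result a [simulate_tumor_pde()] result.
#' @param a1,a2 threshold fractions for the width measurements.
#' @param level front-tracking level; defaults to `a2 * pmax` of the final
#'   profile.
#' @param fit_window fraction interval of the time span used for the speed
#'   fit (default the last 40%).
#' @param boundary_margin error if the front comes within this distance of
#'   the far boundary during the fit window.
#' @return list with `speed`, `p_max`, `L1`, `L2` (all nondimensional) and
#'   the per-time `front` data frame.
#' @export
measure_wave <- function(result, a1 = 0.9, a2 = 0.1, level = NULL,
                         fit_window = c(0.6, 1), boundary_margin = 5) {
  stopifnot(inherits(result, "gbm_simulation"))
  p_fin <- result$p[nrow(result$p), ]
  p_max <- max(p_fin)
  if (is.null(level)) level <- a2 * p_max
  u <- result$p + result$q
  front <- apply(u, 1, .outer_crossing, x = result$x, level = level)
  tspan <- range(result$times)
  sel <- result$times >= tspan[1] + fit_window[1] * diff(tspan) &
    result$times <= tspan[1] + fit_window[2] * diff(tspan)
  if (any(!is.finite(front[sel])))
    stop("measurement error: front not detectable throughout the fit window",
         call. = FALSE)
  if (max(front[sel]) > max(result$x) - boundary_margin)
    stop("measurement error: front too close to the far boundary",
         call. = FALSE)
  fit <- lm(front[sel] ~ result$times[sel])
  # widths from the final p profile
  xo1 <- .outer_crossing(p_fin, result$x, a1 * p_max)
  xi1 <- .inner_crossing(p_fin, result$x, a1 * p_max)
  xo2 <- .outer_crossing(p_fin, result$x, a2 * p_max)
  list(speed = unname(coef(fit)[2]), p_max = p_max,
       L1 = xo1 - xi1, L2 = xo2 - xo1,
       front = data.frame(time = result$times, x = front))
}

# outermost downward crossing of v through level, linear interpolation
.outer_crossing <- function(v, x, level) {
  above <- which(v >= level)
  if (!length(above)) return(NA_real_)
  i <- max(above)
  if (i == length(v)) return(x[i])
  x[i] + (x[i + 1] - x[i]) * (v[i] - level) / (v[i] - v[i + 1])
}

# innermost upward crossing (rim's core-side edge) of v through level
.inner_crossing <- function(v, x, level) {
  above <- which(v >= level)
  if (!length(above)) return(NA_real_)
  i <- min(above)
  if (i == 1) return(x[1])
  x[i] - (x[i] - x[i - 1]) * (v[i] - level) / (v[i] - v[i - 1])
}
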