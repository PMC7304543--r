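# Approximate traveling-wave profile in the phase plane.
#
# After the Canosa reduction the wave profile satisfies
#   dp/dw = delta(w) / (rho_hat * g(w)) - 1,    p(1) = 0,
# so p(w) is a plain quadrature of the right-hand side from w = 1 downward.
# The trajectory leaves (p, w) = (0, 1), peaks where delta(w) = rho_hat*g(w),
# and returns to p = 0 at the necrotic plateau w = w*. For linear-like growth
# responses w* can be exponentially small in rho_hat, so the small-w tail is
# integrated in u = log(w).

.W_SPLIT <- 1e-2   # below this, quadrature runs in log(w)

# quadrature with a slightly relaxed retry; R's integrate() occasionally
# reports roundoff trouble at very tight tolerances
.quad <- function(f, lower, upper, rel.tol = 1e-11, abs.tol = 1e-13) {
  out <- tryCatch(
    integrate(f, lower, upper, rel.tol = rel.tol, abs.tol = abs.tol,
              subdivisions = 1000L, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(out) || !is.finite(out$value))
    out <- integrate(f, lower, upper, rel.tol = 1e-8, abs.tol = 1e-10,
                     subdivisions = 2000L, stop.on.error = TRUE)
  out$value
}

#' Approximate traveling-wave profile p(w)
#'
#' Integrates the reduced phase-plane equation
#' `dp/dw = delta(w) / (rho_hat * g(w)) - 1` from `w = 1` (where `p = 0`)
#' downward, returning the profile of proliferating-cell density against the
#' growth factor. The peak `p_max` occurs where `delta(w) = rho_hat * g(w)`;
#' the profile returns to zero at the necrotic plateau `w = w*`.
#'
#' @param rho_hat dimensionless ratio `rho / k` (> 0).
#' @param model a [gbm_model()] (or a list with callables `g`, `delta`).
#' @param tol relative quadrature tolerance for evaluating `p(w)`.
#' @return an object of class `gbm_profile`: a list with the vectorized
#'   profile function `p` (of `w`), `rho_hat`, `w_star`, `w_peak`, `p_max`,
#'   the response functions, and a dense `table` (columns `w`, `p`, `z`) for
#'   plotting and export. The wave coordinate `z` increases into the tumor
#'   and is anchored at `z = 0` at the peak.
#' @examples
#' pr <- wave_profile(1, gbm_shapes("linear"))
#' pr$p_max                      # 0.30685...
#' pr$w_peak                     # 1 / (1 + rho_hat) = 0.5 for linear shapes
#' @export
wave_profile <- function(rho_hat, model = gbm_shapes("table"), tol = 1e-11) {
  if (!is.finite(rho_hat) || rho_hat <= 0)
    stop("rho_hat must be positive", call. = FALSE)
  r <- as_responses(model)
  g <- r$g; delta <- r$delta
  integrand <- function(s) 1 - delta(s) / (rho_hat * g(s))
  # p on the main range, with a cached base value for the log-substituted tail
  p_base <- NULL
  p_fun <- function(w) {
    vapply(w, function(wi) {
      if (wi >= 1) return(0)
      if (wi >= .W_SPLIT)
        return(.quad(integrand, wi, 1, rel.tol = tol))
      if (is.null(p_base))
        p_base <<- .quad(integrand, .W_SPLIT, 1, rel.tol = tol)
      tail <- .quad(function(u) integrand(exp(u)) * exp(u),
                    log(wi), log(.W_SPLIT), rel.tol = tol)
      p_base + tail
    }, numeric(1))
  }
  # peak: delta - rho_hat*g is positive at 0+ and negative at 1-
  w_peak <- uniroot(function(w) delta(w) - rho_hat * g(w),
                    c(1e-14, 1 - 1e-14), tol = 1e-15)$root
  p_max <- p_fun(w_peak)
  if (!is.finite(p_max) || p_max <= 0)
    stop("profile error: no positive peak found; ",
         "check that the model satisfies the response constraints",
         call. = FALSE)
  w_star <- .find_below(p_fun, 0, w_peak)
  prof <- structure(
    list(rho_hat = rho_hat, model = model, p = p_fun,
         w_star = w_star, w_peak = w_peak, p_max = p_max,
         g = g, delta = delta, tol = tol),
    class = "gbm_profile")
  prof$table <- .profile_table(prof)
  prof
}

# Solve p(w) = target on the core side (w* < w < w_peak) by a geometric
# downward scan followed by uniroot in log(w); robust when w* is tiny.
.find_below <- function(p_fun, target, w_peak, w_min = 1e-300) {
  hi <- w_peak
  lo <- w_peak * 0.7
  repeat {
    if (p_fun(lo) <= target) break
    hi <- lo
    lo <- lo * 0.5
    if (lo < w_min)
      stop("profile error: p(w) never returns to the target level above w = 0",
           call. = FALSE)
  }
  u <- uniroot(function(t) p_fun(exp(t)) - target, c(log(lo), log(hi)),
               tol = 1e-13)
  exp(u$root)
}

# Dense (w, p, z) table spanning (w*, 1) for plotting/export; z = 0 at the
# peak, increasing into the tumor. z diverges logarithmically at both ends,
# so the table stops a small margin inside.
.profile_table <- function(prof, n = 301) {
  lo <- prof$w_star + (prof$w_peak - prof$w_star) * 1e-4
  hi <- 1 - (1 - prof$w_peak) * 1e-4
  w <- sort(unique(c(seq(lo, hi, length.out = n), prof$w_peak)))
  p <- prof$p(w)
  dzdw <- 1 / (prof$rho_hat * p * prof$g(w))
  # cumulative trapezoid for z, anchored at the peak
  z <- c(0, cumsum((dzdw[-1] + dzdw[-length(w)]) / 2 * diff(w)))
  z <- -(z - z[which.min(abs(w - prof$w_peak))])
  data.frame(w = w, p = p, z = z)
}

#' @export
print.gbm_profile <- function(x, ...) {
  cat("Approximate traveling-wave profile (phase-plane reduction)\n")
  cat(sprintf("  rho_hat = %g, nondimensional speed c = 2*sqrt(rho_hat) = %g\n",
              x$rho_hat, wave_speed(x$rho_hat)))
  cat(sprintf("  w* = %g, w_peak = %g, p_max = %g\n",
              x$w_star, x$w_peak, x$p_max))
  invisible(x)
}

#' @export
plot.gbm_profile <- function(x, which = c("w", "z"), ...) {
  which <- match.arg(which)
  if (which == "w") {
    plot(x$table$w, x$table$p, type = "l", xlab = "growth factor w",
         ylab = "proliferating density p", ...)
    abline(v = c(x$w_star, x$w_peak), lty = 3, col = "grey40")
  } else {
    plot(x$table$z, x$table$p, type = "l", xlab = "wave coordinate z (inward)",
         ylab = "proliferating density p", ...)
  }
  invisible(x)
}

#' Threshold crossings of the wave profile
#'
#' Finds the two growth-factor levels at which the profile crosses
#' `a * p_max`: `w_in` on the tumor-core side (between `w*` and the peak) and
#' `w_out` on the leading-edge side (between the peak and 1).
#'
#' @param profile a [wave_profile()] object.
#' @param a threshold as a fraction of `p_max`, in (0, 1).
#' @return named numeric vector `c(w_in, w_out)`.
#' @export
threshold_crossings <- function(profile, a) {
  stopifnot(inherits(profile, "gbm_profile"))
  if (!is.finite(a) || a <= 0 || a >= 1)
    stop("threshold fraction a must lie strictly in (0, 1)", call. = FALSE)
  target <- a * profile$p_max
  w_in <- .find_below(profile$p, target, profile$w_peak)
  w_out <- uniroot(function(w) profile$p(w) - target,
                   c(profile$w_peak, 1 - 1e-13), tol = 1e-14)$root
  c(w_in = w_in, w_out = w_out)
}

#' Dimensionless width integrals of the rim and the edema
#'
#' With the wave coordinate satisfying `dz/dw = -1 / (rho_hat * p(w) * g(w))`,
#' computes the dimensionless z-spans `I1` (proliferating rim: between the two
#' `a1 * p_max` crossings) and `I2` (edematous rim: from the leading-edge `a1`
#' crossing out to the `a2 * p_max` crossing), plus their ratio
#' `f = I1 / I2`. Dimensional widths follow as
#' `l_i = (2 * sqrt(D * rho) / k) * I_i`.
#'
#' @param profile a [wave_profile()] object.
#' @param a1 T1 (contrast-enhancement) detection threshold fraction.
#' @param a2 T2 (edema) detection threshold fraction; `0 < a2 < a1 < 1`.
#' @return an object of class `gbm_profile_metrics`: list with `w_a1_in`,
#'   `w_a1_out`, `w_a2_out`, `I1`, `I2`, `f_ratio`, `a1`, `a2`, `rho_hat`.
#' @export
width_integrals <- function(profile, a1 = 0.9, a2 = 0.1) {
  stopifnot(inherits(profile, "gbm_profile"))
  if (!(a2 > 0 && a2 < a1 && a1 < 1))
    stop("thresholds must satisfy 0 < a2 < a1 < 1", call. = FALSE)
  cr1 <- threshold_crossings(profile, a1)
  w_a2_out <- uniroot(function(w) profile$p(w) - a2 * profile$p_max,
                      c(cr1[["w_out"]], 1 - 1e-13), tol = 1e-14)$root
  integrand <- function(w) 1 / (profile$rho_hat * profile$p(w) * profile$g(w))
  I1 <- .width_quad(integrand, cr1[["w_in"]], cr1[["w_out"]])
  I2 <- .width_quad(integrand, cr1[["w_out"]], w_a2_out)
  structure(
    list(w_a1_in = cr1[["w_in"]], w_a1_out = cr1[["w_out"]],
         w_a2_out = w_a2_out, I1 = I1, I2 = I2, f_ratio = I1 / I2,
         a1 = a1, a2 = a2, rho_hat = profile$rho_hat),
    class = "gbm_profile_metrics")
}

# adaptive quadrature for the width integrand, with a u = log(1 - w)
# substitution fallback for near-edge intervals where p is small
.width_quad <- function(integrand, lower, upper) {
  val <- tryCatch(.quad(integrand, lower, upper, rel.tol = 1e-10, abs.tol = 1e-12),
                  error = function(e) NULL)
  if (is.null(val) || !is.finite(val) || val < 0) {
    f_u <- function(u) integrand(1 - exp(u)) * exp(u)
    val <- .quad(f_u, log(1 - upper), log(1 - lower),
                 rel.tol = 1e-10, abs.tol = 1e-12)
  }
  if (!is.finite(val) || val <= 0)
    stop("numeric error: width quadrature failed to converge", call. = FALSE)
  val
}

#' @export
print.gbm_profile_metrics <- function(x, ...) {
  cat(sprintf("Profile width metrics at rho_hat = %g (a1 = %g, a2 = %g)\n",
              x$rho_hat, x$a1, x$a2))
  cat(sprintf("  crossings: w_a1_in = %.6g, w_a1_out = %.6g, w_a2_out = %.6g\n",
              x$w_a1_in, x$w_a1_out, x$w_a2_out))
  cat(sprintf("  I1 = %.8g, I2 = %.8g, f = I1/I2 = %.8g\n",
              x$I1, x$I2, x$f_ratio))
  invisible(x)
}

#' Identifiability ratio f(rho_hat)
#'
#' Composes [wave_profile()] and [width_integrals()] and returns the ratio
#' `I1 / I2` of the dimensionless rim and edema widths. Because the
#' dimensional prefactor `2 * sqrt(D * rho) / k` cancels in the ratio, `f`
#' depends only on `rho_hat`, the response shapes and the two thresholds; its
#' strict monotonicity is what makes `rho_hat` identifiable from the measured
#' `L1 / L2`.
#'
#' @param rho_hat one or more positive values of `rho / k`.
#' @inheritParams width_integrals
#' @param model a [gbm_model()].
#' @return numeric vector of ratios, one per `rho_hat`.
#' @export
f_of_rho_hat <- function(rho_hat, model = gbm_shapes("table"),
                         a1 = 0.9, a2 = 0.1) {
  vapply(rho_hat, function(rh) {
    width_integrals(wave_profile(rh, model), a1 = a1, a2 = a2)$f_ratio
  }, numeric(1))
}

#' Nondimensional minimum wave speed
#'
#' The linearization at the wave head gives the minimum (and, numerically,
#' the asymptotic) nondimensional speed `c = 2 * sqrt(rho_hat)`; in
#' dimensional units the front advances at `2 * sqrt(rho * D)`.
#'
#' @param rho_hat positive value(s) of `rho / k`.
#' @return `2 * sqrt(rho_hat)`.
#' @export
wave_speed <- function(rho_hat) {
  if (any(!is.finite(rho_hat)) || any(rho_hat <= 0))
    stop("rho_hat must be positive", call. = FALSE)
  2 * sqrt(rho_hat)
}

#' Export a profile table to CSV
#'
#' Writes the dense `(w, p, z)` table of a [wave_profile()] to a CSV file for
#' plotting or debugging.
#'
#' @param profile a `gbm_profile`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_profile <- function(profile, path) {
  stopifnot(inherits(profile, "gbm_profile"))
  write.csv(profile$table, path, row.names = FALSE)
  invisible(path)
}
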