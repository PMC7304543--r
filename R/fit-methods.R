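# S3 methods for gbm_fit objects.

#' @export
print.gbm_fit <- function(x, ...) {
  cat(sprintf("GBM growth-model fit (%s protocol), patient %s\n",
              gsub("_", "-", x$method), x$observation$patient_id))
  cat(sprintf("  D   = %.4f mm^2/day\n  rho = %.4f /day\n  k   = %.4f /day\n",
              x$D, x$rho, x$k))
  cat(sprintf("  rho_hat = %.4f, wave speed c = %.4f mm/day, tumor age = %.0f days\n",
              x$rho_hat, x$c, x$tumor_age))
  invisible(x)
}

#' @export
coef.gbm_fit <- function(object, ...) {
  c(D = object$D, rho = object$rho, k = object$k)
}

#' @export
summary.gbm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.gbm_fit")
}

#' @export
print.summary.gbm_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  response shapes: g = B(w; %g, %g), delta = 1 - B(w; %g, %g)\n",
              f$model$alpha_g, f$model$beta_g, f$model$alpha_d, f$model$beta_d))
  cat(sprintf("  profile: w* = %.4g, w_peak = %.4g, p_max = %.4g\n",
              f$profile$w_star, f$profile$w_peak, f$profile$p_max))
  cat(sprintf("  widths: l1 = %.4f (L1 = %.4f), l2 = %.4f (L2 = %.4f) mm\n",
              f$l1, f$observation$L1, f$l2, f$observation$L2))
  cat(sprintf("  detectability radii at t*: R*_1 = %.3f, R*_2 = %.3f mm\n",
              f$R_star1, f$R_star2))
  cat("  residuals (per matching equation):\n")
  print(signif(f$residuals, 4))
  invisible(x)
}

#' @export
residuals.gbm_fit <- function(object, ...) object$residuals

#' Predicted radii over tumor age
#'
#' Predicts the three compartment radii as functions of tumor age: during
#' the exponential phase (`t <= t_star`) the detectability radii of the
#' growing point source; afterwards, linear front expansion at the wave
#' speed with the rim and edema widths carried along.
#'
#' @param object a `gbm_fit`.
#' @param times tumor ages in days; defaults to a grid from `t_star` to the
#'   estimated age.
#' @param ... unused.
#' @return a data frame with columns `time`, `R0`, `R1`, `R2` (mm; `NA`
#'   where a compartment is not yet detectable or not yet formed).
#' @export
predict.gbm_fit <- function(object, times = NULL, ...) {
  cfg <- object$config
  if (is.null(times))
    times <- seq(cfg$t_star, max(object$tumor_age, cfg$t_star + 1),
                 length.out = 50)
  p_max <- object$profile$p_max
  out <- lapply(times, function(t) {
    if (t <= cfg$t_star) {
      r1 <- .rstar(object$D, object$rho, cfg$a1, cfg, p_max = p_max, t = t)
      r2 <- .rstar(object$D, object$rho, cfg$a2, cfg, p_max = p_max, t = t)
      c(NA_real_, r1, r2)
    } else {
      r1 <- object$R_star1 + object$c * (t - cfg$t_star)
      c(max(r1 - object$l1, 0), r1, r1 + object$l2)
    }
  })
  out <- do.call(rbind, out)
  data.frame(time = times, R0 = out[, 1], R1 = out[, 2], R2 = out[, 3])
}

#' Plot a fitted wave profile in dimensional coordinates
#'
#' Draws the proliferating-cell density against radial distance (mm), with
#' the detection thresholds and the patient's measured radii overlaid.
#'
#' @param x a `gbm_fit`.
#' @param ... passed to [plot()].
#' @export
plot.gbm_fit <- function(x, ...) {
  tab <- x$profile$table
  # dimensional distance: r = R1 - (z - z(w_a1_out)) * c / (2 rho_hat) scale;
  # z is in units of c * sqrt(D/k) (dz/dw carries a 1/c factor folded into z)
  len <- 2 * sqrt(x$D * x$rho) / x$k   # mm per unit z
  z_rim <- approx(tab$w, tab$z, xout = x$metrics$w_a1_out)$y
  r <- x$observation$R1 - (tab$z - z_rim) * len
  ok <- is.finite(r)
  plot(r[ok], tab$p[ok], type = "l", xlab = "radial distance (mm)",
       ylab = "proliferating density p", ...)
  abline(h = c(x$config$a1, x$config$a2) * x$profile$p_max,
         lty = 3, col = "grey50")
  abline(v = c(x$observation$R0, x$observation$R1, x$observation$R2),
         lty = 2, col = "firebrick")
  legend("topright", bty = "n",
         legend = c("wave profile", "thresholds", "measured radii"),
         lty = c(1, 3, 2), col = c("black", "grey50", "firebrick"))
  invisible(x)
}

#' Simulate synthetic observations from a fitted model
#'
#' Draws `nsim` forward-modelled patient observations from the fitted
#' `(D, rho, k)` at the estimated tumor age, optionally perturbing the radii
#' with independent Gaussian noise.
#'
#' @param object a `gbm_fit`.
#' @param nsim number of observations.
#' @param seed optional RNG seed (the global RNG state is restored on exit).
#' @param noise_sd standard deviation of the additive radius noise, mm.
#' @param ... unused.
#' @return a data frame in the patient-observation schema, with the truth
#'   parameters attached as attribute `"truth"`.
#' @export
simulate.gbm_fit <- function(object, nsim = 1, seed = NULL, noise_sd = 0, ...) {
  synthetic_cohort(n = nsim,
                   truth = data.frame(D = object$D, rho = object$rho,
                                      k = object$k, age = object$tumor_age),
                   config = object$config, model = object$model,
                   noise_sd = noise_sd, seed = seed)$patients
}
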