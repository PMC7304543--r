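# Inversion of image-derived measurements into patient-specific D, rho, k.

#' Imaging configuration
#'
#' Bundles the imaging thresholds and early-growth constants used by both
#' estimation protocols: `a1` and `a2` are the T1 (contrast-enhancement) and
#' T2 (edema) detection thresholds as fractions of the peak proliferating
#' density; `p0` is the density of the initial point source (dimensionless
#' cell density); `t_star` is the duration, in days, of the initial
#' exponential-growth phase before the tumor expands as a traveling wave.
#'
#' @param a1,a2 detection threshold fractions, `0 < a2 < a1 < 1`.
#' @param p0 initial point-source density (> 0).
#' @param t_star end of the exponential phase, days (> 0).
#' @param threshold_times_pmax if `TRUE`, the early-phase detectability radii
#'   use thresholds `a_i * p_max` rather than `a_i` alone (the default keeps
#'   the plain `a_i` threshold in the point-source formula).
#' @param width_equation which width equation anchors the `D(rho)`
#'   substitution in the single-scan protocol: `"l1"` (proliferating rim,
#'   default) or `"l2"` (edema).
#' @param rho_hat_bracket search interval for the ratio inversion.
#' @param rho_bracket search interval (per day) for the single-scan age
#'   equation.
#' @return an object of class `gbm_config`.
#' @export
imaging_config <- function(a1 = 0.9, a2 = 0.1, p0 = 0.02, t_star = 60,
                           threshold_times_pmax = FALSE,
                           width_equation = c("l1", "l2"),
                           rho_hat_bracket = c(0.05, 50),
                           rho_bracket = c(1e-3, 2)) {
  if (!(a2 > 0 && a2 < a1 && a1 < 1))
    stop("thresholds must satisfy 0 < a2 < a1 < 1", call. = FALSE)
  if (p0 <= 0) stop("p0 must be positive", call. = FALSE)
  if (t_star <= 0) stop("t_star must be positive", call. = FALSE)
  structure(
    list(a1 = a1, a2 = a2, p0 = p0, t_star = t_star,
         threshold_times_pmax = isTRUE(threshold_times_pmax),
         width_equation = match.arg(width_equation),
         rho_hat_bracket = sort(rho_hat_bracket),
         rho_bracket = sort(rho_bracket)),
    class = "gbm_config")
}

#' Patient observation: three MRI-derived radii
#'
#' One patient's equivalent-sphere radii (mm): `R0` of the necrotic core,
#' `R1` to the edge of the contrast-enhancing rim, `R2` to the outer edge of
#' edema. `L1 = R1 - R0` and `L2 = R2 - R1` are derived. An image-derived
#' front velocity `V` (mm/day, from two scans) is optional; when present, its
#' `velocity_source` records which radius it was tracked on.
#'
#' @param R0,R1,R2 radii in mm, `0 < R0 < R1 < R2`.
#' @param V optional front velocity, mm/day (> 0).
#' @param patient_id identifier.
#' @param velocity_source `"R1"` or `"R2"`; required bookkeeping when `V` is
#'   given, because the radius used to difference the scans matters for the
#'   tumor-age estimate.
#' @return an object of class `gbm_observation`.
#' @export
patient_observation <- function(R0, R1, R2, V = NULL, patient_id = "patient",
                                velocity_source = c("R1", "R2")) {
  if (any(!is.finite(c(R0, R1, R2))) || R0 <= 0 || R1 <= R0 || R2 <= R1)
    stop("radii must satisfy 0 < R0 < R1 < R2", call. = FALSE)
  if (!is.null(V)) {
    if (!is.finite(V) || V <= 0) stop("V must be positive", call. = FALSE)
    velocity_source <- match.arg(velocity_source)
  } else velocity_source <- NA_character_
  structure(
    list(patient_id = as.character(patient_id),
         R0 = R0, R1 = R1, R2 = R2, V = V,
         L1 = R1 - R0, L2 = R2 - R1,
         velocity_source = velocity_source),
    class = "gbm_observation")
}

#' @export
print.gbm_observation <- function(x, ...) {
  cat(sprintf("Patient %s: R0 = %g, R1 = %g, R2 = %g mm (L1 = %g, L2 = %g)\n",
              x$patient_id, x$R0, x$R1, x$R2, x$L1, x$L2))
  if (!is.null(x$V))
    cat(sprintf("  front velocity V = %g mm/day (from %s)\n",
                x$V, x$velocity_source))
  invisible(x)
}

#' Equivalent-sphere radii from segmentation volumes
#'
#' Converts segmented compartment volumes (necrotic core, enhancing rim,
#' edema) to the three concentric radii, assuming spherical geometry: the
#' cumulative volumes map to `R_i = (3 V_cum / (4 pi))^(1/3)`.
#'
#' @param v_necrotic,v_enhancing,v_edema compartment volumes in mm^3 (>= 0).
#' @return named numeric vector `c(R0, R1, R2)` in mm.
#' @examples
#' volumes_to_radii(4 * pi / 3, 4 * pi / 3 * 7, 4 * pi / 3 * 19)  # 1, 2, 3
#' @export
volumes_to_radii <- function(v_necrotic, v_enhancing, v_edema) {
  v <- c(v_necrotic, v_enhancing, v_edema)
  if (any(!is.finite(v)) || any(v < 0))
    stop("volumes must be non-negative", call. = FALSE)
  cum <- cumsum(v)
  r <- (3 * cum / (4 * pi))^(1 / 3)
  c(R0 = r[1], R1 = r[2], R2 = r[3])
}

#' Invert the identifiability ratio for rho_hat
#'
#' Solves `f(rho_hat) = L1 / L2` for `rho_hat` by bracketed root-finding on
#' the (strictly monotone) ratio of the dimensionless width integrals. If the
#' target ratio lies outside the range of `f` on the bracket, an
#' identifiability error naming the attainable interval is raised.
#'
#' @param ratio measured `L1 / L2` (> 0).
#' @param model a [gbm_model()].
#' @param config an [imaging_config()].
#' @param bracket optional override of the `rho_hat` search interval.
#' @return the unique `rho_hat` with `f(rho_hat) = ratio` (relative tolerance
#'   about 1e-9), with the evaluated bracket attached as attribute
#'   `"bracket"`.
#' @export
solve_rho_hat <- function(ratio, model = gbm_shapes("table"),
                          config = imaging_config(), bracket = NULL) {
  if (!is.finite(ratio) || ratio <= 0)
    stop("L1/L2 ratio must be positive", call. = FALSE)
  br <- if (is.null(bracket)) config$rho_hat_bracket else sort(bracket)
  ffun <- function(rh) f_of_rho_hat(rh, model, config$a1, config$a2) - ratio
  flo <- ffun(br[1]); fhi <- ffun(br[2])
  if (flo * fhi > 0) {
    cond <- structure(
      class = c("gbmwave_identifiability_error", "error", "condition"),
      list(message = sprintf(
        paste0("identifiability error: L1/L2 = %.6g is outside the attainable",
               " range [%.6g, %.6g] of f on rho_hat in [%g, %g]"),
        ratio, flo + ratio, fhi + ratio, br[1], br[2]),
        call = sys.call(-1)))
    stop(cond)
  }
  root <- uniroot(ffun, br, tol = 1e-12)$root
  attr(root, "bracket") <- br
  root
}

#' Detectability radius at the end of the exponential phase
#'
#' During the initial phase the tumor is modelled as exponential growth from
#' a Gaussian point source,
#' `p(r, t) = p0 * (4 pi D t)^(-3/2) * exp(rho t - r^2 / (4 D t))`.
#' Thresholding at level `a_i` and evaluating at `t = t_star` gives the
#' radius at which the tumor first becomes detectable on the corresponding
#' MRI sequence:
#' `R_i = sqrt(4 D rho t*^2 - 4 D t* log(a_i (4 pi D t*)^(3/2) / p0))`.
#'
#' @param D diffusion coefficient, mm^2/day.
#' @param rho proliferation rate, per day.
#' @param a_i detection threshold (fraction; multiplied by `p_max` when the
#'   configuration sets `threshold_times_pmax` and `p_max` is supplied).
#' @param config an [imaging_config()].
#' @param p_max optional wave-profile peak density, used only with
#'   `threshold_times_pmax = TRUE`.
#' @param t time at which to evaluate the radius; defaults to `config$t_star`.
#' @return the radius in mm.
#' @export
exponential_phase_radius <- function(D, rho, a_i, config = imaging_config(),
                                     p_max = NULL, t = NULL) {
  r <- .rstar(D, rho, a_i, config, p_max = p_max, t = t)
  if (is.na(r))
    stop("tumor undetectable at t*: negative radicand in the point-source ",
         "detectability radius", call. = FALSE)
  r
}

# NA-returning workhorse (scans over rho need a non-throwing variant)
.rstar <- function(D, rho, a_i, config, p_max = NULL, t = NULL) {
  ts <- if (is.null(t)) config$t_star else t
  thr <- a_i
  if (config$threshold_times_pmax) {
    if (is.null(p_max))
      stop("p_max required when threshold_times_pmax = TRUE", call. = FALSE)
    thr <- a_i * p_max
  }
  rad <- 4 * D * rho * ts^2 -
    4 * D * ts * log(thr * (4 * pi * D * ts)^(3 / 2) / config$p0)
  if (!is.finite(rad) || rad < 0) return(NA_real_)
  sqrt(rad)
}

# ---- estimation protocols ---------------------------------------------------

# shared first stage: rho_hat from the ratio, profile metrics, and the
# width-anchored relation sqrt(D * rho) = rho * Lw / (2 * rho_hat * Iw)
.stage_ratio <- function(obs, config, model) {
  rho_hat <- solve_rho_hat(obs$L1 / obs$L2, model, config)
  prof <- wave_profile(rho_hat, model)
  met <- width_integrals(prof, config$a1, config$a2)
  if (config$width_equation == "l1") {
    Lw <- obs$L1; Iw <- met$I1
  } else {
    Lw <- obs$L2; Iw <- met$I2
  }
  list(rho_hat = as.numeric(rho_hat), bracket = attr(rho_hat, "bracket"),
       profile = prof, metrics = met, Lw = Lw, Iw = Iw)
}

#' Two-scan estimation of D, rho, k
#'
#' When a front velocity `V` is available from two sequential scans, the
#' three matching conditions `l1 = L1`, `l2 = L2`, `c = V` are solved in
#' closed form after the ratio inversion: `rho_hat` from `f(rho_hat) =
#' L1/L2`, then `k = V * I1 / L1` (so the dimensional rim width matches
#' exactly), `rho = rho_hat * k`, and `D = (V / 2)^2 / rho` from the speed
#' law `c = 2 * sqrt(rho * D)`.
#'
#' @param obs a [patient_observation()] carrying `V`.
#' @param config an [imaging_config()].
#' @param model a [gbm_model()].
#' @return a `gbm_fit` object; see [gbm_fit()].
#' @export
estimate_two_scan <- function(obs, config = imaging_config(),
                              model = gbm_shapes("table")) {
  stopifnot(inherits(obs, "gbm_observation"))
  if (is.null(obs$V)) stop("two-scan estimation requires V", call. = FALSE)
  st <- .stage_ratio(obs, config, model)
  k <- obs$V * st$Iw / st$Lw
  rho <- st$rho_hat * k
  D <- (obs$V / 2)^2 / rho
  .finish_fit(obs, config, model, st, D = D, rho = rho, k = k,
              method = "two_scan", age_residual = NA_real_)
}

#' Single-scan estimation of D, rho, k
#'
#' With only one scan the velocity equation is replaced by an age-consistency
#' condition: the tumor grows exponentially from a point source until
#' `t_star` (reaching detectability radii `R*_1`, `R*_2`) and as a traveling
#' wave afterwards, so the ages inferred from `R1` and `R2` must agree. This
#' reduces to `R2 - R1 = R*_2(D(rho), rho) - R*_1(D(rho), rho)`, solved for
#' `rho` by bracketed root-finding after substituting the width-anchored
#' relation `D(rho) = rho * (L1 / (2 rho_hat I1))^2`. The detectability
#' boundary (where the point-source radicand vanishes) is located first and
#' the scan is refined just above it, because the residual can clear zero
#' only in a narrow sliver beyond that square-root singularity.
#'
#' @inheritParams estimate_two_scan
#' @return a `gbm_fit` object; see [gbm_fit()].
#' @export
estimate_single_scan <- function(obs, config = imaging_config(),
                                 model = gbm_shapes("table")) {
  stopifnot(inherits(obs, "gbm_observation"))
  st <- .stage_ratio(obs, config, model)
  lambda <- (st$Lw / (2 * st$rho_hat * st$Iw))^2   # D(rho) = lambda * rho
  p_max <- st$profile$p_max
  h <- function(rho) {
    D <- lambda * rho
    r1 <- .rstar(D, rho, config$a1, config, p_max = p_max)
    r2 <- .rstar(D, rho, config$a2, config, p_max = p_max)
    if (is.na(r1) || is.na(r2)) return(NA_real_)
    (r2 - r1) - (obs$R2 - obs$R1)
  }
  rho <- .solve_age_equation(h, config$rho_bracket)
  D <- lambda * rho
  k <- rho / st$rho_hat
  .finish_fit(obs, config, model, st, D = D, rho = rho, k = k,
              method = "single_scan", age_residual = h(rho))
}

# Root of the age-equation residual on a log grid, with refinement just above
# the detectability boundary (NA region -> valid region transition).
.solve_age_equation <- function(h, bracket, n_grid = 200L) {
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = n_grid))
  vals <- vapply(grid, h, numeric(1))
  # refine each NA -> finite transition: bisect the boundary, then add a
  # geometric ladder of points just above it (h has a sqrt singularity there)
  extra <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (is.na(vals[i]) && !is.na(vals[i + 1])) {
      lo <- grid[i]; hi <- grid[i + 1]
      for (it in 1:80) {
        mid <- sqrt(lo * hi)
        if (is.na(h(mid))) lo <- mid else hi <- mid
      }
      extra <- c(extra, hi * (1 + 10^seq(-12, -1, length.out = 24)))
    }
  }
  if (length(extra)) {
    grid <- c(grid, extra[extra <= bracket[2]])
    ord <- order(grid)
    grid <- grid[ord]
    vals <- c(vals, vapply(extra[extra <= bracket[2]], h, numeric(1)))[ord]
  }
  ok <- which(!is.na(vals))
  root <- NA_real_
  for (j in seq_along(ok)[-1]) {
    i1 <- ok[j - 1]; i2 <- ok[j]
    if (i2 - i1 == 1 || all(is.na(vals[(i1 + 1):(i2 - 1)])))
      if (vals[i1] * vals[i2] <= 0) {
        root <- uniroot(h, c(grid[i1], grid[i2]), tol = 1e-14)$root
        break
      }
  }
  if (is.na(root)) {
    cond <- structure(
      class = c("gbmwave_estimation_error", "error", "condition"),
      list(message = paste0(
        "estimation error: the age-equation residual has no sign change in ",
        sprintf("rho in [%g, %g]; residual range [%.4g, %.4g] on %d valid points",
                bracket[1], bracket[2],
                suppressWarnings(min(vals, na.rm = TRUE)),
                suppressWarnings(max(vals, na.rm = TRUE)), length(ok)),
        " (residual curve attached as attr 'residual_curve')"),
        call = sys.call(-1)))
    attr(cond, "residual_curve") <- data.frame(rho = grid, residual = vals)
    stop(cond)
  }
  root
}

# assemble the fit object and its diagnostics
.finish_fit <- function(obs, config, model, st, D, rho, k, method,
                        age_residual) {
  c_speed <- 2 * sqrt(rho * D)
  pref <- 2 * sqrt(D * rho) / k
  l1 <- pref * st$metrics$I1
  l2 <- pref * st$metrics$I2
  p_max <- st$profile$p_max
  rstar1 <- .rstar(D, rho, config$a1, config, p_max = p_max)
  tumor_age <- if (is.na(rstar1)) NA_real_ else
    config$t_star + (obs$R1 - rstar1) / c_speed
  res <- c(l1_minus_L1 = l1 - obs$L1, l2_minus_L2 = l2 - obs$L2,
           third_equation = if (method == "two_scan")
             c_speed - obs$V else age_residual)
  fitted_model <- gbm_model(model$alpha_g, model$beta_g,
                            model$alpha_d, model$beta_d, rho = rho, k = k)
  structure(
    list(D = D, rho = rho, k = k, rho_hat = st$rho_hat, c = c_speed,
         tumor_age = tumor_age, residuals = res,
         bracket_used = st$bracket, method = method,
         observation = obs, config = config, model = fitted_model,
         profile = st$profile, metrics = st$metrics,
         l1 = l1, l2 = l2, R_star1 = rstar1,
         R_star2 = .rstar(D, rho, config$a2, config, p_max = p_max)),
    class = "gbm_fit")
}

#' Fit the GBM growth model to one patient's MRI radii
#'
#' The main user-facing estimator. Inverts the three equivalent-sphere radii
#' (necrotic core `R0`, enhancing rim `R1`, edema extent `R2`) — and, if
#' available, the image-derived front velocity `V` — into the patient's
#' diffusion coefficient `D` (mm^2/day), proliferation rate `rho` (/day) and
#' death rate `k` (/day).
#'
#' The inversion proceeds in two stages. First the ratio of the rim and edema
#' widths, `L1 / L2`, determines `rho_hat = rho / k` through the strictly
#' monotone ratio `f(rho_hat)` of the dimensionless profile width integrals.
#' Second, with `V` present, the remaining two parameters follow in closed
#' form from the rim-width match and the speed law (`method = "two_scan"`);
#' without `V`, an age-consistency equation between the early
#' exponential-growth phase and the traveling-wave phase is solved for `rho`
#' (`method = "single_scan"`).
#'
#' @param observation a [patient_observation()], or radii may be given
#'   directly via `R0`, `R1`, `R2` (and optionally `V`).
#' @param R0,R1,R2,V used only when `observation` is missing.
#' @param config an [imaging_config()].
#' @param model a [gbm_model()] giving the response shapes; the default
#'   ([gbm_shapes("table")][gbm_shapes]) is the shape choice matched to the
#'   published six-patient cohort.
#' @param method `"auto"` (two-scan when `V` is present), `"single_scan"`,
#'   or `"two_scan"`.
#' @return an object of class `gbm_fit` with components `D`, `rho`, `k`,
#'   `rho_hat`, wave speed `c` (mm/day), `tumor_age` (days), per-equation
#'   `residuals`, and the underlying profile and width metrics. Methods:
#'   `print`, `summary`, `coef`, `predict` (radii over time), `plot`,
#'   `residuals`, `simulate` (synthetic observations from the fit).
#' @examples
#' \donttest{
#' fit <- gbm_fit(R0 = 14.87, R1 = 20.73, R2 = 27.77)
#' coef(fit)          # D, rho, k
#' }
#' @export
gbm_fit <- function(observation = NULL, R0 = NULL, R1 = NULL, R2 = NULL,
                    V = NULL, config = imaging_config(),
                    model = gbm_shapes("table"),
                    method = c("auto", "single_scan", "two_scan")) {
  method <- match.arg(method)
  if (is.null(observation))
    observation <- patient_observation(R0, R1, R2, V = V)
  if (method == "auto")
    method <- if (!is.null(observation$V)) "two_scan" else "single_scan"
  switch(method,
         two_scan = estimate_two_scan(observation, config, model),
         single_scan = estimate_single_scan(observation, config, model))
}
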