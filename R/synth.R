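# Forward-modelling of synthetic patient observations from known parameters.

#' Generate one synthetic patient observation
#'
#' Forward-models the three MRI radii from ground-truth parameters
#' `(D, rho, k)` and a tumor age: the enhancing-rim radius is the
#' exponential-phase detectability radius at `t_star` plus traveling-wave
#' expansion, `R1 = R*_1 + c (age - t_star)` with `c = 2 sqrt(rho D)`; the
#' rim and edema widths come from the wave-profile width integrals,
#' `R0 = R1 - l1` and `R2 = R1 + l2`; and the emitted velocity is the wave
#' speed, `V = c`. With `generator = "pde"` the widths and speed are instead
#' measured from a full cross-diffusion simulation at the truth's `rho_hat`
#' and rescaled to mm/day, so the observation carries the (small)
#' approximation gap between the phase-plane profile and the PDE.
#'
#' @param D,rho,k ground-truth parameters (mm^2/day, /day, /day).
#' @param age tumor age in days (> `config$t_star`).
#' @param config an [imaging_config()].
#' @param model a [gbm_model()] giving the response shapes.
#' @param generator `"approximation"` (phase-plane widths, default) or
#'   `"pde"`.
#' @param noise_sd optional standard deviation (mm) of independent additive
#'   Gaussian noise on each radius; `0` for a deterministic observation.
#' @param seed optional RNG seed; the global RNG state is restored on exit,
#'   and a recorded seed reproduces noisy draws exactly.
#' @param patient_id identifier.
#' @param ... passed to [simulate_tumor_pde()] when `generator = "pde"`.
#' @return a [patient_observation()] with the truth attached as attribute
#'   `"truth"` (a named list including the profile metrics used).
#' @export
synthetic_patient <- function(D, rho, k, age, config = imaging_config(),
                              model = gbm_shapes("table"),
                              generator = c("approximation", "pde"),
                              noise_sd = 0, seed = NULL,
                              patient_id = "synthetic", ...) {
  generator <- match.arg(generator)
  stopifnot(D > 0, rho > 0, k > 0)
  if (age <= config$t_star)
    stop("tumor age must exceed t_star", call. = FALSE)
  rho_hat <- rho / k
  prof <- wave_profile(rho_hat, model)
  met <- width_integrals(prof, config$a1, config$a2)
  if (generator == "approximation") {
    pref <- 2 * sqrt(D * rho) / k
    l1 <- pref * met$I1
    l2 <- pref * met$I2
    c_speed <- 2 * sqrt(rho * D)
  } else {
    sim <- simulate_tumor_pde(rho_hat = rho_hat, model = model, ...)
    mw <- measure_wave(sim, a1 = config$a1, a2 = config$a2)
    len <- sqrt(D / k)                      # mm per nondimensional length
    l1 <- len * mw$L1
    l2 <- len * mw$L2
    c_speed <- len * k * mw$speed           # mm/day
  }
  R_star1 <- exponential_phase_radius(D, rho, config$a1, config,
                                      p_max = prof$p_max)
  R1 <- R_star1 + c_speed * (age - config$t_star)
  radii <- c(R1 - l1, R1, R1 + l2)
  if (noise_sd > 0) {
    radii <- .with_seed(seed, radii + rnorm(3, sd = noise_sd))
    radii <- sort(radii)
  }
  if (radii[1] <= 0)
    stop("R0 <= 0 after forward modelling; ",
         "reduce noise_sd or increase the tumor age", call. = FALSE)
  obs <- patient_observation(radii[1], radii[2], radii[3], V = c_speed,
                             patient_id = patient_id,
                             velocity_source = "R1")
  attr(obs, "truth") <- list(D = D, rho = rho, k = k, age = age,
                             rho_hat = rho_hat, c = c_speed,
                             l1 = l1, l2 = l2, R_star1 = R_star1,
                             generator = generator,
                             noise_sd = noise_sd, seed = seed)
  obs
}

# run expr-with-noise under a local RNG seed, restoring global state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else on.exit(rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  expr
}

#' Generate a synthetic cohort
#'
#' Draws `n` ground-truth parameter sets (uniformly over the given ranges, or
#' recycled from a supplied data frame) and forward-models one observation
#' each. Two data frames are returned side by side: the observations in the
#' patient-record schema and the ground truth.
#'
#' @param n number of patients.
#' @param truth either `NULL` (draw uniformly from `ranges`) or a data frame
#'   with columns `D`, `rho`, `k`, `age` (recycled to `n` rows).
#' @param ranges named list of `c(min, max)` ranges for `D`, `rho`, `k`,
#'   `age` used when `truth` is `NULL`. The defaults bracket the published
#'   patient estimates while staying inside the region where the tumor is
#'   already detectable at `t_star` under the default thresholds (the
#'   point-source radicand is positive) and `rho / k` stays in the
#'   identifiable bracket.
#' @param config,model,generator,noise_sd as in [synthetic_patient()].
#' @param seed RNG seed governing both the parameter draws and the noise.
#' @return list with data frames `patients` (columns `patient_id`, `R0_mm`,
#'   `R1_mm`, `R2_mm`, `V_mm_per_day`, `velocity_source`) and `truth`.
#' @export
synthetic_cohort <- function(n, truth = NULL,
                             ranges = list(D = c(0.1, 0.6),
                                           rho = c(0.23, 0.30),
                                           k = c(0.05, 0.25),
                                           age = c(90, 250)),
                             config = imaging_config(),
                             model = gbm_shapes("table"),
                             generator = "approximation",
                             noise_sd = 0, seed = NULL) {
  draws <- .with_seed(seed, {
    if (is.null(truth)) {
      data.frame(D = runif(n, ranges$D[1], ranges$D[2]),
                 rho = runif(n, ranges$rho[1], ranges$rho[2]),
                 k = runif(n, ranges$k[1], ranges$k[2]),
                 age = runif(n, ranges$age[1], ranges$age[2]))
    } else truth[rep_len(seq_len(nrow(truth)), n), , drop = FALSE]
    # noise seeds derived per patient so each row reproduces independently
  })
  noise_seeds <- if (!is.null(seed)) seed + seq_len(n) else rep(list(NULL), n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    obs <- synthetic_patient(draws$D[i], draws$rho[i], draws$k[i],
                             draws$age[i], config = config, model = model,
                             generator = generator, noise_sd = noise_sd,
                             seed = if (is.null(seed)) NULL else noise_seeds[[i]],
                             patient_id = sprintf("synth_%03d", i))
    rows[[i]] <- data.frame(patient_id = obs$patient_id, R0_mm = obs$R0,
                            R1_mm = obs$R1, R2_mm = obs$R2,
                            V_mm_per_day = obs$V,
                            velocity_source = obs$velocity_source)
  }
  truth_df <- cbind(patient_id = sprintf("synth_%03d", seq_len(n)),
                    draws, row.names = NULL)
  list(patients = do.call(rbind, rows), truth = truth_df)
}

#' Project a truth onto the estimator-consistent manifold
#'
#' The single-scan protocol uses both the traveling-wave widths and the
#' exponential-phase age correction; an arbitrary `(D, rho, k)` does not in
#' general satisfy both at once (the forward model emitting `R2 = R1 + l2`
#' over-determines the radii), so exact single-scan round trips hold only
#' for parameter sets in the image of the estimator. This helper produces
#' such a set: it forward-models one noise-free observation from the given
#' truth and re-estimates. Because the estimator is a retraction
#' (estimate(generate(estimate(x))) = estimate(x)), regenerating from the
#' returned parameters and estimating again recovers them exactly.
#'
#' @inheritParams synthetic_patient
#' @return named list with `D`, `rho`, `k`, `age` on the consistent manifold.
#' @export
consistent_truth <- function(D, rho, k, age, config = imaging_config(),
                             model = gbm_shapes("table")) {
  obs <- synthetic_patient(D, rho, k, age, config = config, model = model)
  obs$V <- NULL
  fit <- estimate_single_scan(obs, config = config, model = model)
  list(D = fit$D, rho = fit$rho, k = fit$k, age = fit$tumor_age)
}
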