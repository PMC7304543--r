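#' Growth/death response model from the beta-CDF family
#'
#' Defines the birth and death responses of the tumor growth model. The per
#' capita birth rate of proliferating cells is `rho * g(w)` and the rate of
#' transition to quiescence is `k * delta(w)`, where `w = 1 - p - q` is the
#' available growth factor. Both responses are taken from the beta-CDF family:
#' `g(w) = B(w; alpha_g, beta_g)` and `delta(w) = 1 - B(w; alpha_d, beta_d)`,
#' with `B` the regularized incomplete beta function. This family guarantees
#' the structural constraints `g(0) = 0`, `g(1) = 1`, `delta(0) = 1`,
#' `delta(1) = 0`, `g` non-decreasing and `delta` non-increasing, so that the
#' birth rate at saturating growth factor is exactly `rho` and the death rate
#' in its complete absence is exactly `k`.
#'
#' @param alpha_g,beta_g positive shape parameters of the growth response.
#' @param alpha_d,beta_d positive shape parameters of the death response.
#' @param rho proliferation rate at `w = 1`, per day. May be `NA` when only
#'   the dimensionless profile is needed.
#' @param k death (quiescence) rate at `w = 0`, per day. May be `NA`.
#' @return an object of class `gbm_model`.
#' @seealso [gbm_shapes()] for named preset shape choices,
#'   [growth_response()], [death_response()], [validate_constraints()].
#' @examples
#' m <- gbm_model(2, 2, 1, 3, rho = 0.2, k = 0.06)
#' growth_response(m, c(0, 0.5, 1))
#' death_response(m, c(0, 0.5, 1))
#' @export
gbm_model <- function(alpha_g = 2, beta_g = 2, alpha_d = 1, beta_d = 3,
                      rho = NA_real_, k = NA_real_) {
  shp <- c(alpha_g = alpha_g, beta_g = beta_g, alpha_d = alpha_d, beta_d = beta_d)
  if (any(!is.finite(shp)) || any(shp <= 0))
    stop("all shape parameters must be positive and finite", call. = FALSE)
  if (!is.na(rho) && rho <= 0) stop("rho must be positive", call. = FALSE)
  if (!is.na(k) && k <= 0) stop("k must be positive", call. = FALSE)
  structure(
    list(alpha_g = alpha_g, beta_g = beta_g, alpha_d = alpha_d, beta_d = beta_d,
         rho = rho, k = k),
    class = "gbm_model")
}

#' @export
print.gbm_model <- function(x, ...) {
  cat("GBM growth/death response model (beta-CDF family)\n")
  cat(sprintf("  g(w)     = B(w; %g, %g)\n", x$alpha_g, x$beta_g))
  cat(sprintf("  delta(w) = 1 - B(w; %g, %g)\n", x$alpha_d, x$beta_d))
  if (!is.na(x$rho) || !is.na(x$k))
    cat(sprintf("  rho = %s /day, k = %s /day, rho_hat = %s\n",
                format(x$rho), format(x$k),
                ifelse(is.na(x$rho) || is.na(x$k), "NA", format(x$rho / x$k))))
  invisible(x)
}

#' Named preset shape choices
#'
#' Returns a [gbm_model()] for one of the candidate response-function shapes:
#' `"linear"` (`Beta(1,1)` for both responses, the analytically tractable
#' case), `"sigmoid"` (`Beta(2,2)` for both), `"concave-up"` (`Beta(3,1)`),
#' `"concave-down"` (`Beta(1,3)`), and `"table"` — sigmoidal growth
#' `B(w; 2, 2)` with cubic death `delta(w) = (1 - w)^3` — the combination that
#' reproduces the published six-patient parameter table and the package
#' default.
#'
#' @param name preset name.
#' @param rho,k optional dimensional rates, per day.
#' @return a `gbm_model`.
#' @export
gbm_shapes <- function(name = c("table", "linear", "sigmoid",
                                "concave-up", "concave-down"),
                       rho = NA_real_, k = NA_real_) {
  name <- match.arg(name)
  shp <- switch(name,
    "table"        = c(2, 2, 1, 3),
    "linear"       = c(1, 1, 1, 1),
    "sigmoid"      = c(2, 2, 2, 2),
    "concave-up"   = c(3, 1, 3, 1),
    "concave-down" = c(1, 3, 1, 3))
  gbm_model(shp[1], shp[2], shp[3], shp[4], rho = rho, k = k)
}

#' Candidate shape combinations
#'
#' The candidate response-function choices: each of the four beta-CDF shapes
#' (linear, sigmoidal, concave up, concave down) applied jointly to the
#' growth and death responses, plus the `"table"` pairing. The
#' identifiability ratio `f(rho_hat)` is strictly monotone for each of
#' these. Note that monotonicity is a property of the pairing, not of the
#' shapes individually: crossing a concave-down growth response with a
#' linear or concave-up death response produces a non-monotone `f` at small
#' `rho_hat`, so such mixes are excluded from the candidate set (they can
#' still be built explicitly with [gbm_model()], and their monotonicity
#' audited with [f_of_rho_hat()]).
#'
#' @return a named list of `gbm_model` objects.
#' @export
gbm_shape_candidates <- function() {
  base <- list("linear" = c(1, 1), "sigmoid" = c(2, 2),
               "concave-up" = c(3, 1), "concave-down" = c(1, 3))
  out <- lapply(base, function(s) gbm_model(s[1], s[2], s[1], s[2]))
  out$table <- gbm_shapes("table")
  out
}

#' Growth response g(w)
#'
#' Evaluates `g(w) = B(w; alpha_g, beta_g)`, the fraction of the maximal
#' proliferation rate available at growth-factor level `w`.
#'
#' @param model a [gbm_model()].
#' @param w growth-factor level(s) in `[0, 1]`.
#' @return values in `[0, 1]`; exactly 0 at `w = 0` and 1 at `w = 1`.
#' @export
growth_response <- function(model, w) {
  stopifnot(inherits(model, "gbm_model"))
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("w must lie in [0, 1]", call. = FALSE)
  pbeta(w, model$alpha_g, model$beta_g)
}

#' Death response delta(w)
#'
#' Evaluates `delta(w) = 1 - B(w; alpha_d, beta_d)`, the fraction of the
#' maximal quiescence rate at growth-factor level `w`.
#'
#' @inheritParams growth_response
#' @return values in `[0, 1]`; exactly 1 at `w = 0` and 0 at `w = 1`.
#' @export
death_response <- function(model, w) {
  stopifnot(inherits(model, "gbm_model"))
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("w must lie in [0, 1]", call. = FALSE)
  pbeta(w, model$alpha_d, model$beta_d, lower.tail = FALSE)
}

# Internal: resolve a model (or a list with callables g, delta) into the pair
# of response functions used by the profile and PDE modules. Tests may inject
# arbitrary callables; the public configuration surface is the beta family.
as_responses <- function(model) {
  if (inherits(model, "gbm_model")) {
    list(g = function(w) pbeta(w, model$alpha_g, model$beta_g),
         delta = function(w) pbeta(w, model$alpha_d, model$beta_d,
                                   lower.tail = FALSE))
  } else if (is.list(model) && is.function(model$g) && is.function(model$delta)) {
    model[c("g", "delta")]
  } else {
    stop("`model` must be a gbm_model or a list with functions g and delta",
         call. = FALSE)
  }
}

#' Validate the structural constraints on the response functions
#'
#' Checks, on a uniform grid of `n_grid` points in `[0, 1]`, that the growth
#' response is non-decreasing, the death response non-increasing, and that the
#' endpoint conditions `g(0) = 0`, `g(1) = 1`, `delta(0) = 1`, `delta(1) = 0`
#' hold (so that there is more birth than death at saturating growth factor
#' and only death in its absence). A report is always returned; nothing is
#' thrown on failure.
#'
#' @param model a [gbm_model()] or a list with callables `g` and `delta`
#'   (arbitrary responses can be audited this way).
#' @param n_grid number of grid points (at least 2).
#' @return a data frame of class `gbm_validation` with one row per condition
#'   and columns `condition`, `pass`, `detail`.
#' @export
validate_constraints <- function(model, n_grid = 201) {
  stopifnot(n_grid >= 2)
  r <- as_responses(model)
  w <- seq(0, 1, length.out = n_grid)
  gv <- r$g(w); dv <- r$delta(w)
  tol <- 1e-12
  res <- data.frame(
    condition = c("g(0) = 0", "g(1) = 1", "delta(0) = 1", "delta(1) = 0",
                  "g non-decreasing", "delta non-increasing",
                  "rho*g(1) >= k*delta(1)", "k*delta(0) > rho*g(0)"),
    pass = c(abs(gv[1]) <= tol,
             abs(gv[n_grid] - 1) <= tol,
             abs(dv[1] - 1) <= tol,
             abs(dv[n_grid]) <= tol,
             all(diff(gv) >= -tol),
             all(diff(dv) <= tol),
             abs(dv[n_grid]) <= tol,         # reduces to delta(1) = 0
             abs(gv[1]) <= tol && dv[1] > 0),# reduces to g(0) = 0, delta(0) > 0
    stringsAsFactors = FALSE)
  res$detail <- c(sprintf("g(0) = %.3g", gv[1]),
                  sprintf("g(1) = %.3g", gv[n_grid]),
                  sprintf("delta(0) = %.3g", dv[1]),
                  sprintf("delta(1) = %.3g", dv[n_grid]),
                  sprintf("min increment %.3g", min(diff(gv))),
                  sprintf("max increment %.3g", max(diff(dv))),
                  sprintf("delta(1) = %.3g", dv[n_grid]),
                  sprintf("g(0) = %.3g, delta(0) = %.3g", gv[1], dv[1]))
  class(res) <- c("gbm_validation", class(res))
  res
}

#' @export
print.gbm_validation <- function(x, ...) {
  status <- ifelse(x$pass, "PASS", "FAIL")
  cat("Response-function constraint report:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-24s %s\n", status[i], x$condition[i], x$detail[i]))
  invisible(x)
}
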