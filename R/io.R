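# Patient-record and configuration I/O, cohort estimation, run manifests.
# Units are fixed: radii in mm, volumes in mm^3, rates per day. CSV files are
# comma-separated UTF-8 with a header row and "." as the decimal separator.

#' Read patient records from CSV
#'
#' Accepts either radius columns (`patient_id`, `R0_mm`, `R1_mm`, `R2_mm`,
#' optional `V_mm_per_day`, `velocity_source`) or segmentation-volume columns
#' (`v_necrotic_mm3`, `v_enhancing_mm3`, `v_edema_mm3`), which are routed
#' through [volumes_to_radii()]. Rows violating the ordering invariant
#' `0 < R0 < R1 < R2` (or with non-numeric cells) are rejected with a
#' per-row reason; valid rows are kept and the run continues.
#'
#' @param path CSV file path.
#' @return a data frame of validated records (columns `patient_id`, `R0_mm`,
#'   `R1_mm`, `R2_mm`, `V_mm_per_day`, `velocity_source`), with rejected rows
#'   as attribute `"rejected"` (data frame of `row`, `patient_id`, `reason`).
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  has_radii <- all(c("R0_mm", "R1_mm", "R2_mm") %in% names(raw))
  has_vols <- all(c("v_necrotic_mm3", "v_enhancing_mm3", "v_edema_mm3") %in%
                    names(raw))
  if (!has_radii && !has_vols)
    stop("missing columns: need R0_mm/R1_mm/R2_mm or ",
         "v_necrotic_mm3/v_enhancing_mm3/v_edema_mm3", call. = FALSE)
  if (is.null(raw$patient_id))
    raw$patient_id <- sprintf("row_%d", seq_len(nrow(raw)))
  keep <- list(); rejected <- list()
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    reason <- NULL
    radii <- tryCatch({
      if (has_radii) {
        as.numeric(c(row$R0_mm, row$R1_mm, row$R2_mm))
      } else {
        v <- as.numeric(c(row$v_necrotic_mm3, row$v_enhancing_mm3,
                          row$v_edema_mm3))
        if (any(is.na(v)) || any(v < 0)) stop("non-numeric")
        unname(volumes_to_radii(v[1], v[2], v[3]))
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(radii) || any(is.na(radii))) {
      reason <- "non-numeric"
    } else if (!(radii[1] > 0 && radii[1] < radii[2] && radii[2] < radii[3])) {
      reason <- "ordering"
    }
    V <- suppressWarnings(as.numeric(row$V_mm_per_day))
    if (length(V) == 0 || is.na(V)) V <- NA_real_
    if (is.null(reason) && !is.na(V) && V <= 0) reason <- "velocity"
    if (is.null(reason)) {
      keep[[length(keep) + 1]] <- data.frame(
        patient_id = as.character(row$patient_id),
        R0_mm = radii[1], R1_mm = radii[2], R2_mm = radii[3],
        V_mm_per_day = V,
        velocity_source = if (is.null(row$velocity_source) ||
                              is.na(row$velocity_source)) NA_character_
                          else as.character(row$velocity_source),
        stringsAsFactors = FALSE)
    } else {
      rejected[[length(rejected) + 1]] <- data.frame(
        row = i, patient_id = as.character(row$patient_id), reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(keep)) do.call(rbind, keep) else
    data.frame(patient_id = character(), R0_mm = numeric(),
               R1_mm = numeric(), R2_mm = numeric(),
               V_mm_per_day = numeric(), velocity_source = character())
  attr(out, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(row = integer(), patient_id = character(),
               reason = character())
  if (nrow(attr(out, "rejected")))
    warning(sprintf("%d row(s) rejected; see attr(., 'rejected')",
                    nrow(attr(out, "rejected"))), call. = FALSE)
  out
}

#' Estimate parameters for a cohort
#'
#' Runs [gbm_fit()] on every row of a patient table (as returned by
#' [read_patients()] or [synthetic_cohort()]). Per-row estimation failures
#' (identifiability, undetectability) are recorded in the `status` column and
#' do not stop the run.
#'
#' @param patients data frame with columns `patient_id`, `R0_mm`, `R1_mm`,
#'   `R2_mm` and optionally `V_mm_per_day`, `velocity_source`.
#' @param config an [imaging_config()].
#' @param model a [gbm_model()].
#' @param method passed to [gbm_fit()].
#' @return a data frame with one row per patient: `patient_id`,
#'   `D_mm2_per_day`, `rho_per_day`, `k_per_day`, `rho_hat`, `c_mm_per_day`,
#'   `tumor_age_days`, `residual` (worst per-equation misfit), `status`
#'   (`"ok"` or the error class). A run manifest (config snapshot, package
#'   version, timestamps, per-row status) is attached as attribute
#'   `"manifest"`.
#' @export
estimate_cohort <- function(patients, config = imaging_config(),
                            model = gbm_shapes("table"), method = "auto") {
  t_start <- Sys.time()
  empty <- data.frame(patient_id = character(), D_mm2_per_day = numeric(),
                      rho_per_day = numeric(), k_per_day = numeric(),
                      rho_hat = numeric(), c_mm_per_day = numeric(),
                      tumor_age_days = numeric(), residual = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    pr <- patients[i, ]
    V <- if ("V_mm_per_day" %in% names(pr) && !is.na(pr$V_mm_per_day))
      pr$V_mm_per_day else NULL
    fit <- tryCatch({
      obs <- patient_observation(pr$R0_mm, pr$R1_mm, pr$R2_mm, V = V,
                                 patient_id = pr$patient_id,
                                 velocity_source =
                                   if (!is.null(V) &&
                                       !is.na(pr$velocity_source))
                                     pr$velocity_source else "R1")
      gbm_fit(obs, config = config, model = model, method = method)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      status <- if (inherits(fit, "gbmwave_identifiability_error"))
        "identifiability error"
      else if (grepl("undetectable", conditionMessage(fit)))
        "undetectable"
      else paste("error:", conditionMessage(fit))
      data.frame(patient_id = as.character(pr$patient_id),
                 D_mm2_per_day = NA_real_, rho_per_day = NA_real_,
                 k_per_day = NA_real_, rho_hat = NA_real_,
                 c_mm_per_day = NA_real_, tumor_age_days = NA_real_,
                 residual = NA_real_, status = status,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = as.character(pr$patient_id),
                 D_mm2_per_day = fit$D, rho_per_day = fit$rho,
                 k_per_day = fit$k, rho_hat = fit$rho_hat,
                 c_mm_per_day = fit$c, tumor_age_days = fit$tumor_age,
                 residual = max(abs(fit$residuals)), status = "ok",
                 stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "manifest") <- list(
    config = unclass(config),
    shapes = unclass(model)[c("alpha_g", "beta_g", "alpha_d", "beta_d")],
    tool_version = as.character(packageVersion("gbmwave")),
    started = format(t_start), finished = format(Sys.time()),
    per_patient_status = setNames(out$status, out$patient_id))
  out
}

#' Write cohort estimates (and manifest) to CSV/JSON
#'
#' @param estimates the result of [estimate_cohort()].
#' @param path output CSV path; the manifest is written alongside as
#'   `<path>.manifest.json` when present.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  write.csv(estimates, path, row.names = FALSE)
  man <- attr(estimates, "manifest")
  if (!is.null(man))
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an imaging/shape configuration from JSON
#'
#' The JSON schema mirrors [imaging_config()]: top-level keys `a1`, `a2`,
#' `p0`, `t_star_days`, `threshold_times_pmax`, `width_equation`,
#' `rho_hat_bracket`, `rho_bracket`, plus an optional `shapes` object with
#' `alpha_g`, `beta_g`, `alpha_d`, `beta_d`.
#'
#' @param path JSON file path.
#' @return list with components `config` (a `gbm_config`) and `model`
#'   (a `gbm_model`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  j <- tryCatch(jsonlite::fromJSON(path),
                error = function(e)
                  stop("schema error: malformed JSON config (",
                       conditionMessage(e), ")", call. = FALSE))
  take <- function(key, default) if (!is.null(j[[key]])) j[[key]] else default
  cfg <- imaging_config(
    a1 = take("a1", 0.9), a2 = take("a2", 0.1), p0 = take("p0", 0.02),
    t_star = take("t_star_days", 60),
    threshold_times_pmax = take("threshold_times_pmax", FALSE),
    width_equation = take("width_equation", "l1"),
    rho_hat_bracket = take("rho_hat_bracket", c(0.05, 50)),
    rho_bracket = take("rho_bracket", c(1e-3, 2)))
  s <- j$shapes
  model <- if (is.null(s)) gbm_shapes("table") else
    gbm_model(s$alpha_g, s$beta_g, s$alpha_d, s$beta_d)
  list(config = cfg, model = model)
}
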