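#' CKD-EPI 2009 creatinine equation constants
#'
#' Published constants of the 2009 CKD-EPI creatinine equation, without the
#' race coefficient (configurable via `race_factor` in [ckd_epi_egfr()]).
#' `kappa` is the sex-specific creatinine knot (mg/dL), `alpha` the
#' sex-specific exponent below the knot, `beta` the shared exponent above it.
#'
#' @return Named list of equation constants.
#' @export
ckd_epi_params <- function() {
  list(
    kappa = c(female = 0.7, male = 0.9),
    alpha = c(female = -0.329, male = -0.411),
    beta = -1.209,
    age_factor = 0.993,
    female_factor = 1.018,
    scale = 141
  )
}

check_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("female", "male", "f", "m"))) {
    stop("`sex` must be 'female'/'male' (or 'f'/'m')", call. = FALSE)
  }
  ifelse(sex %in% c("f", "female"), "female", "male")
}

#' Estimated GFR from serum creatinine (CKD-EPI 2009)
#'
#' @param scr Serum creatinine in mg/dL (positive).
#' @param age Age in years (positive).
#' @param sex "female" or "male" (vectorized, recycled).
#' @param race_factor Optional multiplicative factor (default 1; the race
#'   coefficient of the original equation is omitted).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' ckd_epi_egfr(0.7, 50, "female") # ~101
#' @export
ckd_epi_egfr <- function(scr, age, sex, race_factor = 1) {
  if (any(!is.finite(scr)) || any(scr <= 0)) stop("`scr` must be positive", call. = FALSE)
  if (any(!is.finite(age)) || any(age <= 0)) stop("`age` must be positive", call. = FALSE)
  sex <- check_sex(sex)
  p <- ckd_epi_params()
  kappa <- p$kappa[sex]
  alpha <- p$alpha[sex]
  ratio <- scr / kappa
  egfr <- p$scale * pmin(ratio, 1)^alpha * pmax(ratio, 1)^p$beta *
    p$age_factor^age * race_factor
  unname(egfr * ifelse(sex == "female", p$female_factor, 1))
}

#' Serum creatinine attaining a given eGFR (inverse CKD-EPI)
#'
#' Closed-form piecewise inverse of [ckd_epi_egfr()]; used by the cohort
#' generator to turn simulated eGFR trajectories into creatinine series.
#'
#' @param egfr Target eGFR in mL/min/1.73 m^2 (positive).
#' @inheritParams ckd_epi_egfr
#' @return Serum creatinine in mg/dL such that `ckd_epi_egfr()` returns
#'   `egfr` to within numerical tolerance.
#' @export
creatinine_from_egfr <- function(egfr, age, sex, race_factor = 1) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) stop("`egfr` must be positive", call. = FALSE)
  if (any(!is.finite(age)) || any(age <= 0)) stop("`age` must be positive", call. = FALSE)
  sex <- check_sex(sex)
  p <- ckd_epi_params()
  kappa <- p$kappa[sex]
  alpha <- p$alpha[sex]
  # eGFR at the knot scr = kappa
  base <- p$scale * p$age_factor^age * race_factor *
    ifelse(sex == "female", p$female_factor, 1)
  # below the knot the exponent is alpha (negative), above it beta
  expo <- ifelse(egfr > base, alpha, p$beta)
  unname(kappa * (egfr / base)^(1 / expo))
}

#' CKD stage from eGFR
#'
#' Stages 1 (eGFR >= 90) through 5 (eGFR < 15 mL/min/1.73 m^2).
#'
#' @param egfr Non-negative eGFR values.
#' @return Integer stage 1-5.
#' @export
ckd_stage <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr < 0)) stop("`egfr` must be non-negative", call. = FALSE)
  as.integer(as.character(cut(egfr, breaks = c(-Inf, 15, 30, 60, 90, Inf),
                              labels = 5:1, right = FALSE)))
}

INTERVENTION_TYPES <- c("tolvaptan", "dialysis", "nephrectomy", "transplant")

#' Censor eGFR measurements affected by clinical interventions
#'
#' All measurements on or after a patient's earliest intervention date
#' (tolvaptan start, dialysis, nephrectomy, transplant) are removed, since
#' such values no longer reflect the natural disease course. A removal log
#' records counts and reasons per patient.
#'
#' @param egfr_series Data frame with columns `patient_id`, `date` (Date or
#'   ISO-8601 string), `egfr`.
#' @param interventions Data frame with columns `patient_id`, `type`,
#'   `date`; may be empty.
#' @return List with `series` (censored data frame) and `removal_log`
#'   (data frame `patient_id`, `n_removed`, `reason`).
#' @export
censor_measurements <- function(egfr_series, interventions) {
  stopifnot(all(c("patient_id", "date", "egfr") %in% names(egfr_series)))
  egfr_series$date <- as.Date(egfr_series$date)
  if (is.null(interventions) || nrow(interventions) == 0) {
    return(list(series = egfr_series,
                removal_log = data.frame(patient_id = character(0),
                                         n_removed = integer(0),
                                         reason = character(0),
                                         stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("patient_id", "type", "date") %in% names(interventions)))
  bad <- setdiff(unique(interventions$type), INTERVENTION_TYPES)
  if (length(bad) > 0) {
    stop("unknown intervention type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  interventions$date <- as.Date(interventions$date)

  first <- stats::aggregate(date ~ patient_id, data = interventions, FUN = min)
  # reason = type of the earliest intervention (ties: first listed type)
  reason <- vapply(seq_len(nrow(first)), function(i) {
    sub <- interventions[interventions$patient_id == first$patient_id[i] &
                           interventions$date == first$date[i], , drop = FALSE]
    as.character(sub$type[1])
  }, character(1))
  first$reason <- reason

  keep <- rep(TRUE, nrow(egfr_series))
  log_rows <- list()
  for (i in seq_len(nrow(first))) {
    idx <- egfr_series$patient_id == first$patient_id[i] &
      egfr_series$date >= first$date[i]
    if (any(idx)) {
      keep[idx] <- FALSE
      log_rows[[length(log_rows) + 1]] <- data.frame(
        patient_id = first$patient_id[i], n_removed = sum(idx),
        reason = first$reason[i], stringsAsFactors = FALSE)
    }
  }
  removal_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(patient_id = character(0), n_removed = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(series = egfr_series[keep, , drop = FALSE], removal_log = removal_log)
}

#' Robust annualized eGFR slope for one patient
#'
#' Huber M-estimation (tuning constant 1.345, IRLS) of eGFR on the
#' measurement date in days; the per-day coefficient is multiplied by 365.25
#' to give an annual slope. Falls back to ordinary least squares with
#' `converged = FALSE` if the IRLS does not converge.
#'
#' @param dates Measurement dates (Date or coercible).
#' @param egfr eGFR values, same length as `dates`.
#' @param patient_id Identifier carried through to the result.
#' @return List of class `slope_estimate`: `patient_id`, `intercept`,
#'   `slope_annual`, `n_points`, `converged`.
#' @export
fit_patient_slope <- function(dates, egfr, patient_id = NA_character_) {
  dates <- as.numeric(as.Date(dates))
  if (length(dates) != length(egfr)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(dates) & is.finite(egfr)
  dates <- dates[ok]; egfr <- egfr[ok]
  n <- length(dates)
  if (n < 2) stop("need at least 2 measurements", call. = FALSE)
  if (stats::var(dates) == 0) stop("zero date variance", call. = FALSE)

  fit <- tryCatch(
    suppressWarnings(MASS::rlm(egfr ~ dates, k = 1.345, maxit = 50,
                               acc = 1e-8, method = "M")),
    error = function(e) NULL)
  converged <- !is.null(fit) && isTRUE(fit$converged)
  if (!converged) fit <- stats::lm(egfr ~ dates)
  co <- stats::coef(fit)
  structure(list(patient_id = patient_id,
                 intercept = unname(co[1]),
                 slope_annual = unname(co[2]) * 365.25,
                 n_points = n,
                 converged = converged),
            class = "slope_estimate")
}

#' Per-patient annualized slopes for a cohort
#'
#' Applies [fit_patient_slope()] per patient and [filter_slopes()] to flag
#' inclusion per the analysis rules (>= 3 measurements, slope within
#' \[-10, 5\] mL/min/1.73 m^2 per year).
#'
#' @param egfr_series Data frame `patient_id`, `date`, `egfr` (already
#'   censored if required).
#' @return Data frame with one row per patient: `patient_id`, `intercept`,
#'   `slope_annual`, `n_points`, `converged`, `included`,
#'   `exclusion_reason`.
#' @export
fit_cohort_slopes <- function(egfr_series) {
  ids <- unique(egfr_series$patient_id)
  rows <- lapply(ids, function(id) {
    sub <- egfr_series[egfr_series$patient_id == id, , drop = FALSE]
    if (nrow(sub) < 2) {
      return(data.frame(patient_id = id, intercept = NA_real_,
                        slope_annual = NA_real_, n_points = nrow(sub),
                        converged = NA, stringsAsFactors = FALSE))
    }
    est <- fit_patient_slope(sub$date, sub$egfr, patient_id = id)
    data.frame(patient_id = id, intercept = est$intercept,
               slope_annual = est$slope_annual, n_points = est$n_points,
               converged = est$converged, stringsAsFactors = FALSE)
  })
  filter_slopes(do.call(rbind, rows))
}

#' Apply slope inclusion filters
#'
#' A patient's slope enters downstream analyses iff it rests on at least 3
#' eGFR measurements and lies within \[-10, 5\] mL/min/1.73 m^2 per year
#' (boundaries kept: the removal rule reads strictly "greater than 5 or
#' below -10").
#'
#' @param estimates Data frame with columns `slope_annual` and `n_points`.
#' @return Same data frame plus `included` (logical) and
#'   `exclusion_reason` ("too_few_measurements", "slope_out_of_range" or
#'   NA).
#' @export
filter_slopes <- function(estimates) {
  stopifnot(all(c("slope_annual", "n_points") %in% names(estimates)))
  too_few <- estimates$n_points < 3
  oor <- !too_few & !is.na(estimates$slope_annual) &
    (estimates$slope_annual > 5 | estimates$slope_annual < -10)
  estimates$included <- !too_few & !oor & !is.na(estimates$slope_annual)
  estimates$exclusion_reason <- ifelse(too_few, "too_few_measurements",
                                       ifelse(oor, "slope_out_of_range", NA_character_))
  estimates
}
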