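#' Configuration for the synthetic ADPKD cohort generator
#'
#' Defaults emulate the clinical profile of a large European ADPKD registry
#' cohort: median age about 46 years, ~57% female, baseline eGFR with a
#' median near 66 mL/min/1.73 m^2, mildly negative mean annual slope,
#' roughly annual creatinine measurements over a median follow-up of about
#' 6.8 years, and a realistic rate of tolvaptan initiation during
#' follow-up.
#'
#' @param n_patients Number of patients.
#' @param female_fraction Probability a patient is female.
#' @param age_mean,age_sd Age distribution at baseline (years; truncated to
#'   18-80).
#' @param baseline_egfr_range Uniform range of true baseline eGFR.
#' @param true_slope_mean,true_slope_sd Normal distribution of the true
#'   annual eGFR slope (mL/min/1.73 m^2 per year).
#' @param creatinine_noise_cv Coefficient of variation of the multiplicative
#'   log-normal creatinine measurement noise.
#' @param visits_per_year Scheduled creatinine measurements per year.
#' @param followup_years_median Median follow-up; individual follow-up is
#'   uniform on 0.6-1.4 times the median.
#' @param tolvaptan_prob,dialysis_prob,nephrectomy_prob,transplant_prob
#'   Per-patient probabilities of each intervention occurring during
#'   follow-up.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200,
                          female_fraction = 0.57,
                          age_mean = 46, age_sd = 12,
                          baseline_egfr_range = c(30, 110),
                          true_slope_mean = -2.7, true_slope_sd = 2.5,
                          creatinine_noise_cv = 0.05,
                          visits_per_year = 1,
                          followup_years_median = 6.8,
                          tolvaptan_prob = 0.2,
                          dialysis_prob = 0.01,
                          nephrectomy_prob = 0.015,
                          transplant_prob = 0.01,
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, female_fraction = female_fraction,
              age_mean = age_mean, age_sd = age_sd,
              baseline_egfr_range = baseline_egfr_range,
              true_slope_mean = true_slope_mean, true_slope_sd = true_slope_sd,
              creatinine_noise_cv = creatinine_noise_cv,
              visits_per_year = visits_per_year,
              followup_years_median = followup_years_median,
              tolvaptan_prob = tolvaptan_prob, dialysis_prob = dialysis_prob,
              nephrectomy_prob = nephrectomy_prob,
              transplant_prob = transplant_prob, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  probs <- c("female_fraction", "tolvaptan_prob", "dialysis_prob",
             "nephrectomy_prob", "transplant_prob")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("config field `", p, "` must be a proportion in [0,1]", call. = FALSE)
    }
  }
  if (cfg$n_patients < 1) stop("config field `n_patients` must be >= 1", call. = FALSE)
  if (cfg$creatinine_noise_cv < 0) stop("config field `creatinine_noise_cv` must be >= 0", call. = FALSE)
  if (cfg$visits_per_year <= 0) stop("config field `visits_per_year` must be > 0", call. = FALSE)
  if (cfg$followup_years_median * cfg$visits_per_year < 2) {
    stop("config: follow-up must support >= 3 visits at the stated visit rate",
         call. = FALSE)
  }
  invisible(cfg)
}

STUDY_START <- as.Date("2015-01-01")

#' Generate a synthetic ADPKD cohort
#'
#' Draws patient demographics, a linear true eGFR trajectory per patient,
#' jittered annual visit dates, creatinine derived from the true trajectory
#' through the inverse CKD-EPI map with multiplicative log-normal noise,
#' and intervention events. Height-adjusted TKV is generated so the implied
#' Mayo class correlates with the true slope. The returned ground truth
#' records every generated quantity for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return List with `clinical` (patient_id, sex, birth_date, age,
#'   baseline_egfr, httkv_ml_per_m, genotype), `creatinine` (patient_id,
#'   date, scr_mg_dl), `interventions` (patient_id, type, date), and
#'   `ground_truth` (per-patient true slope, true baseline eGFR,
#'   intervention dates).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 18), 80)
  baseline_egfr <- stats::runif(n, config$baseline_egfr_range[1],
                                config$baseline_egfr_range[2])
  true_slope <- stats::rnorm(n, config$true_slope_mean, config$true_slope_sd)
  followup <- config$followup_years_median * stats::runif(n, 0.6, 1.4)

  # theoretical kidney growth rate correlated with slope severity, so Mayo
  # class carries (noisy) prognostic signal; centered so classes spread
  # over 1B-1D with 1C most common, as in registry cohorts
  growth <- pmin(pmax(0.033 + 0.008 * (-true_slope - 2.7) / 2.5 +
                        stats::rnorm(n, 0, 0.011), 0.001), 0.09)
  httkv <- 150 * exp(growth * age)
  genotype <- sample(c("PKD1_truncating", "PKD1_nontruncating", "PKD2"),
                     n, replace = TRUE, prob = c(0.55, 0.17, 0.28))

  sdlog <- sqrt(log(1 + config$creatinine_noise_cv^2))

  creat_rows <- vector("list", n)
  for (i in seq_len(n)) {
    n_visits <- max(3, floor(followup[i] * config$visits_per_year) + 1)
    sched_days <- (seq_len(n_visits) - 1) / config$visits_per_year * 365.25
    jitter <- c(0, stats::runif(n_visits - 1, -30, 30))
    days <- sort(round(sched_days + jitter))
    days <- days[!duplicated(days)]
    t_years <- days / 365.25
    egfr_true <- pmax(baseline_egfr[i] + true_slope[i] * t_years, 2)
    scr_true <- creatinine_from_egfr(egfr_true, age[i], sex[i])
    noise <- if (sdlog > 0) exp(stats::rnorm(length(days), 0, sdlog)) else 1
    creat_rows[[i]] <- data.frame(
      patient_id = ids[i],
      date = STUDY_START + days,
      scr_mg_dl = scr_true * noise,
      stringsAsFactors = FALSE)
  }
  creatinine <- do.call(rbind, creat_rows)

  iv_rows <- list()
  for (type in INTERVENTION_TYPES) {
    prob <- config[[paste0(type, "_prob")]]
    has <- stats::runif(n) < prob
    if (any(has)) {
      # events occur after year 1, within follow-up
      when <- stats::runif(sum(has), 1, pmax(1.5, followup[has]))
      iv_rows[[type]] <- data.frame(
        patient_id = ids[has], type = type,
        date = STUDY_START + round(when * 365.25),
        stringsAsFactors = FALSE)
    }
  }
  interventions <- if (length(iv_rows)) do.call(rbind, iv_rows) else
    data.frame(patient_id = character(0), type = character(0),
               date = as.Date(character(0)), stringsAsFactors = FALSE)
  rownames(interventions) <- NULL

  clinical <- data.frame(
    patient_id = ids, sex = sex,
    birth_date = STUDY_START - round(age * 365.25),
    age = age, baseline_egfr = baseline_egfr,
    httkv_ml_per_m = httkv, genotype = genotype,
    stringsAsFactors = FALSE)

  ground_truth <- list(
    patients = data.frame(patient_id = ids, true_slope = true_slope,
                          true_baseline_egfr = baseline_egfr,
                          age = age, sex = sex, followup_years = followup,
                          stringsAsFactors = FALSE),
    interventions = interventions,
    config = unclass(config))

  list(clinical = clinical, creatinine = creatinine,
       interventions = interventions, ground_truth = ground_truth)
}

#' Default marker effect map
#'
#' Six designated marker proteins with the signs of their association with
#' annual eGFR slope: SERPINF1, FERMT3, CFHR1 and RARRES2 negative; GPX3
#' and AFM positive. Effects are expressed in units of the per-protein
#' residual SD per 1 SD of true slope.
#'
#' @param magnitude Absolute effect size (default 0.5 residual SD).
#' @return Named numeric vector.
#' @export
default_marker_effects <- function(magnitude = 0.5) {
  c(SERPINF1 = -magnitude, GPX3 = magnitude, AFM = magnitude,
    FERMT3 = -magnitude, CFHR1 = -magnitude, RARRES2 = -magnitude)
}

#' Configuration for the synthetic DIA proteome generator
#'
#' @param n_proteins Number of protein groups.
#' @param marker_effects Named vector: log-intensity change (in residual
#'   SDs) per SD of true slope, for slope-linked marker proteins.
#' @param egfr_effects Named vector: log-intensity change (in residual SDs)
#'   per SD of baseline eGFR, for eGFR-dependent proteins: a cystatin-like
#'   CST3 entry (strong negative dependence) and a modest positive
#'   dependence for GPX3.
#' @param n_batches Number of acquisition batches (samples split evenly).
#' @param batch_shift_sd,batch_scale_sd SDs of per-batch additive shifts
#'   and multiplicative (log-scale) spread factors.
#' @param noise_sd Residual log-intensity SD per protein.
#' @param missing_censor_quantile Left-censoring quantile applied per
#'   protein (values below the protein's quantile are reported missing);
#'   default 0 — baseline missingness instead arises at the global
#'   detection limit.
#' @param global_detect_quantile Global detection limit as a quantile of
#'   all log intensities; values below it are missing and identification
#'   confidence degrades near it.
#' @param rarres2_like_missing_rate Censoring quantile applied to RARRES2
#'   specifically, emulating a high-missingness marker.
#' @param outlier_samples Number of samples shifted globally to emulate
#'   failed runs.
#' @param plasma_shift_sd SD of per-protein offsets applied by
#'   [apply_cohort_shift()] when emulating an EDTA-plasma external cohort.
#' @param seed Integer seed.
#' @return List of class `proteome_sim_config`.
#' @export
proteome_sim_config <- function(n_proteins = 200,
                                marker_effects = default_marker_effects(),
                                egfr_effects = c(CST3 = -0.8, GPX3 = 0.3),
                                n_batches = 2,
                                batch_shift_sd = 0.3,
                                batch_scale_sd = 0.1,
                                noise_sd = 0.3,
                                missing_censor_quantile = 0,
                                global_detect_quantile = 0.01,
                                rarres2_like_missing_rate = 0.222,
                                outlier_samples = 0,
                                plasma_shift_sd = 0.5,
                                seed = 1L) {
  stopifnot(n_proteins >= length(marker_effects) + length(egfr_effects),
            missing_censor_quantile >= 0, missing_censor_quantile <= 1,
            global_detect_quantile >= 0, global_detect_quantile <= 1,
            rarres2_like_missing_rate >= 0, rarres2_like_missing_rate <= 1,
            n_batches >= 1, outlier_samples >= 0)
  structure(list(n_proteins = n_proteins, marker_effects = marker_effects,
                 egfr_effects = egfr_effects, n_batches = n_batches,
                 batch_shift_sd = batch_shift_sd,
                 batch_scale_sd = batch_scale_sd, noise_sd = noise_sd,
                 missing_censor_quantile = missing_censor_quantile,
                 global_detect_quantile = global_detect_quantile,
                 rarres2_like_missing_rate = rarres2_like_missing_rate,
                 outlier_samples = outlier_samples,
                 plasma_shift_sd = plasma_shift_sd, seed = as.integer(seed)),
            class = "proteome_sim_config")
}

#' Generate a long-format DIA protein-group report for a cohort
#'
#' One serum sample per patient at baseline (set `followup_samples = TRUE`
#' for an additional follow-up sample per patient, emulating a
#' temporal-validation cohort). Log intensities follow
#' `baseline_p + effect * z(true slope) + effect * z(eGFR) + batch shift +
#' batch scale * noise`; intensities are reported exponentiated with
#' simulated identification q-values, and values below the protein-specific
#' censoring quantile are left out of the report (missing not at random).
#'
#' @param ground_truth Ground truth from [generate_cohort()].
#' @param config A [proteome_sim_config()].
#' @param followup_samples If TRUE, emit a second sample per patient ~2
#'   years after baseline (sharing the patient's slope-linked effects).
#' @return List with `report` (data frame Run, Protein.Group, Genes,
#'   Q.Value, Intensity), `batch` (data frame Run, batch), and
#'   `proteome_truth` (per-protein effects, batch parameters, outlier run
#'   ids, gene names).
#' @export
generate_proteome <- function(ground_truth, config = proteome_sim_config(),
                              followup_samples = FALSE) {
  pats <- ground_truth$patients
  set.seed(config$seed)

  genes <- character(config$n_proteins)
  marker_names <- names(config$marker_effects)
  egfr_names <- setdiff(names(config$egfr_effects), marker_names)
  special <- c(marker_names, egfr_names)
  if (length(special) > config$n_proteins) {
    stop("effect maps reference more proteins than n_proteins", call. = FALSE)
  }
  genes[seq_along(special)] <- special
  filler <- sprintf("G%04d", seq_len(config$n_proteins))
  genes[genes == ""] <- filler[genes == ""]
  pg_ids <- sprintf("PG%04d", seq_len(config$n_proteins))

  runs <- pats$patient_id
  slope_all <- pats$true_slope
  egfr_all <- pats$true_baseline_egfr
  if (followup_samples) {
    runs <- c(runs, paste0(pats$patient_id, "_T2"))
    slope_all <- c(slope_all, pats$true_slope)
    egfr_all <- c(egfr_all, pats$true_baseline_egfr + 2 * pats$true_slope)
  }
  n_s <- length(runs)
  z_slope <- as.numeric(scale(slope_all))
  z_egfr <- as.numeric(scale(egfr_all))

  beta_slope <- stats::setNames(rep(0, config$n_proteins), genes)
  beta_slope[marker_names] <- config$marker_effects
  beta_egfr <- stats::setNames(rep(0, config$n_proteins), genes)
  beta_egfr[names(config$egfr_effects)] <- config$egfr_effects

  base_level <- stats::rnorm(config$n_proteins, 18, 2)
  cq0 <- rep(config$missing_censor_quantile, config$n_proteins)
  names(cq0) <- genes
  if ("RARRES2" %in% genes) cq0["RARRES2"] <- config$rarres2_like_missing_rate
  batch <- rep_len(seq_len(config$n_batches), n_s)
  batch_shift <- stats::rnorm(config$n_batches, 0, config$batch_shift_sd)
  batch_scale <- exp(stats::rnorm(config$n_batches, 0, config$batch_scale_sd))

  sdp <- config$noise_sd
  L <- matrix(base_level, n_s, config$n_proteins, byrow = TRUE) +
    outer(z_slope, beta_slope * sdp) +
    outer(z_egfr, beta_egfr * sdp) +
    matrix(stats::rnorm(n_s * config$n_proteins, 0, sdp), n_s) *
      batch_scale[batch] +
    batch_shift[batch]

  outlier_ids <- character(0)
  if (config$outlier_samples > 0) {
    # failed-run emulation: heterogeneous per-protein distortion (not a
    # global shift, which per-sample normalization would simply absorb)
    oi <- sample(n_s, min(config$outlier_samples, n_s))
    for (o in oi) {
      L[o, ] <- L[o, ] + stats::rnorm(config$n_proteins, 0, 5 * sdp)
    }
    outlier_ids <- runs[oi]
  }

  # left-censoring (MNAR): a global detection limit plus per-protein
  # low-tail quantiles for designated high-missingness proteins
  cq <- cq0
  missing <- matrix(FALSE, n_s, config$n_proteins)
  if (config$global_detect_quantile > 0) {
    missing <- L < stats::quantile(L, config$global_detect_quantile, type = 7)
  }
  for (j in seq_len(config$n_proteins)) {
    if (cq[j] > 0) {
      thr <- stats::quantile(L[, j], cq[j], type = 7)
      missing[, j] <- missing[, j] | L[, j] < thr
    }
  }

  # identification q-values: mostly confident, degrading near the global
  # detection limit, as for real DIA quantification
  qv <- matrix(pmin(stats::rexp(n_s * config$n_proteins, 2000), 1), n_s)
  if (config$global_detect_quantile > 0) {
    near_limit <- L < stats::quantile(L, config$global_detect_quantile) + 0.3
    if (any(near_limit)) {
      qv[near_limit] <- pmin(stats::rexp(sum(near_limit), 100), 1)
    }
  }

  keep <- !missing
  report <- data.frame(
    Run = rep(runs, times = config$n_proteins)[as.vector(keep)],
    Protein.Group = rep(pg_ids, each = n_s)[as.vector(keep)],
    Genes = rep(genes, each = n_s)[as.vector(keep)],
    Q.Value = qv[keep],
    Intensity = exp(L[keep]),
    stringsAsFactors = FALSE)

  proteome_truth <- list(
    genes = genes, pg_ids = pg_ids,
    beta_slope = beta_slope, beta_egfr = beta_egfr,
    base_level = stats::setNames(base_level, genes),
    batch_shift = batch_shift, batch_scale = batch_scale,
    censor_quantile = cq, outlier_runs = outlier_ids,
    runs = runs, batch = stats::setNames(batch, runs))

  list(report = report,
       batch = data.frame(Run = runs, batch = batch, stringsAsFactors = FALSE),
       proteome_truth = proteome_truth)
}

#' Apply a cohort-level per-protein shift to a DIA report
#'
#' Emulates the systematic matrix difference between serum and EDTA-plasma
#' cohorts: one global offset per protein, drawn N(0, plasma_shift_sd), is
#' added on the log-intensity scale, preserving within-cohort correlation
#' structure.
#'
#' @param report Long-format report data frame (Run, Protein.Group, Genes,
#'   Q.Value, Intensity).
#' @param plasma_shift_sd SD of the per-protein log-scale offsets.
#' @param seed Integer seed.
#' @return Shifted report data frame.
#' @export
apply_cohort_shift <- function(report, plasma_shift_sd, seed = 1L) {
  stopifnot(all(c("Genes", "Intensity") %in% names(report)))
  if (plasma_shift_sd == 0) return(report)
  set.seed(as.integer(seed))
  genes <- sort(unique(report$Genes))
  shift <- stats::setNames(stats::rnorm(length(genes), 0, plasma_shift_sd), genes)
  report$Intensity <- report$Intensity * exp(shift[report$Genes])
  report
}

#' Write simulated cohort inputs to plain-text files
#'
#' @param cohort Output of [generate_cohort()].
#' @param proteome Optional output of [generate_proteome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, proteome = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(clinical = file.path(dir, "clinical.csv"),
             creatinine = file.path(dir, "creatinine.csv"),
             interventions = file.path(dir, "interventions.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(cohort$clinical, files["clinical"], row.names = FALSE)
  utils::write.csv(cohort$creatinine, files["creatinine"], row.names = FALSE)
  utils::write.csv(cohort$interventions, files["interventions"], row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth, files["ground_truth"],
                       auto_unbox = TRUE, digits = NA, Date = "ISO8601")
  if (!is.null(proteome)) {
    files <- c(files, report = file.path(dir, "dia_report.tsv"),
               batches = file.path(dir, "batches.csv"))
    utils::write.table(proteome$report, files["report"], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.csv(proteome$batch, files["batches"], row.names = FALSE)
  }
  invisible(files)
}
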