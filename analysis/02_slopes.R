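#!/usr/bin/env Rscript
# Compute per-patient annualized eGFR slopes for each simulated cohort:
# CKD-EPI eGFR from creatinine, censoring of intervention-affected
# measurements, Huber robust slopes, and the inclusion filters
# (>= 3 measurements, slope within [-10, 5]).

suppressPackageStartupMessages(library(pkdprog))

sim <- "results/sim"
out <- "results/slopes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (cohort in c("screening", "temporal", "external")) {
  dir_in <- file.path(sim, cohort)
  clinical <- read.csv(file.path(dir_in, "clinical.csv"))
  creatinine <- read.csv(file.path(dir_in, "creatinine.csv"))
  interventions <- read.csv(file.path(dir_in, "interventions.csv"))

  idx <- match(creatinine$patient_id, clinical$patient_id)
  series <- data.frame(
    patient_id = creatinine$patient_id,
    date = creatinine$date,
    egfr = ckd_epi_egfr(creatinine$scr_mg_dl, clinical$age[idx],
                        clinical$sex[idx]))
  cens <- censor_measurements(series, interventions)
  slopes <- fit_cohort_slopes(cens$series)

  write.csv(slopes, file.path(out, paste0(cohort, "_slopes.csv")),
            row.names = FALSE)
  write.csv(cens$removal_log,
            file.path(out, paste0(cohort, "_removals.csv")),
            row.names = FALSE)

  cat(sprintf(
    "%-9s: %d patients, %d measurements removed (%d patients), %d slopes kept (%d excluded)\n",
    cohort, length(unique(series$patient_id)), sum(cens$removal_log$n_removed),
    nrow(cens$removal_log), sum(slopes$included), sum(!slopes$included)))
}
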