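#!/usr/bin/env Rscript
# Benchmark the fitted Combined Model against the Mayo-class comparator on
# the simulated cohorts: RMSE by CKD stage group, endpoint-eGFR
# prediction, robust agreement lines with bootstrap CIs, within-patient
# repeatability across time points, and rapid-progressor ROC.

suppressPackageStartupMessages(library(pkdprog))

out <- "results/evaluation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L

read_matrix <- function(cohort) {
  d <- read.table(sprintf("results/matrix/%s_matrix.tsv", cohort),
                  sep = "\t", header = TRUE, check.names = FALSE)
  as.matrix(`rownames<-`(d[, -1], d$sample))
}
read_slopes <- function(cohort) {
  s <- read.csv(sprintf("results/slopes/%s_slopes.csv", cohort))
  s <- s[s$included, ]
  setNames(s$slope_annual, s$patient_id)
}
prep_clin <- function(cohort) {
  clin <- read.csv(sprintf("results/sim/%s/clinical.csv", cohort))
  clin$egfr <- clin$baseline_egfr
  clin$mayo_class <- mic_classify(clin$httkv_ml_per_m, clin$age)$mic_class
  clin
}

X <- read_matrix("screening")
slopes <- read_slopes("screening")
clin <- prep_clin("screening")
clin <- clin[clin$patient_id %in% intersect(rownames(X), names(slopes)), ]

spec <- model_spec("combined")
des <- build_design(clin, X, spec, slopes = slopes)
fit <- fit_linear_model(des$design, des$response, scaling = des$scaling)
pred <- predict(fit, des$design)
obs <- des$response
mic <- fit_mic_model(clin$mayo_class[match(des$patient_id, clin$patient_id)],
                     obs)
pred_mic <- predict_mic(mic, clin$mayo_class[match(des$patient_id,
                                                   clin$patient_id)])

base_egfr <- clin$baseline_egfr[match(des$patient_id, clin$patient_id)]
tab <- rbind(
  cbind(model = "combined", rmse_by_stage(obs, pred, base_egfr)),
  cbind(model = "mic", rmse_by_stage(obs, pred_mic, base_egfr)))
write.table(tab, file.path(out, "rmse_by_stage.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("slope RMSE (combined vs MIC):",
    sprintf("%.2f vs %.2f overall\n", rmse(obs, pred), rmse(obs, pred_mic)))
print(tab, row.names = FALSE)

# agreement line of observed on predicted slopes
ag <- agreement_line(obs, pred, n_boot = 1000, seed = seed)
cat(sprintf("agreement line: slope %.2f [%.2f, %.2f], intercept %.2f\n",
            ag$slope, ag$slope_ci[1], ag$slope_ci[2], ag$intercept))

# endpoint eGFR prediction from last observed values
ser <- read.csv("results/sim/screening/creatinine.csv")
ser <- ser[ser$patient_id %in% clin$patient_id, ]
idx <- match(ser$patient_id, clin$patient_id)
ser$egfr <- ckd_epi_egfr(ser$scr_mg_dl, clin$age[idx], clin$sex[idx])
ser <- ser[!is.na(ser$egfr), ]
last <- do.call(rbind, lapply(split(ser, ser$patient_id), function(g) {
  g[which.max(as.Date(g$date)), c("patient_id", "date", "egfr")]
}))
ids <- intersect(des$patient_id, last$patient_id)
li <- match(ids, last$patient_id); di <- match(ids, des$patient_id)
years <- as.numeric(as.Date(last$date[li]) - as.Date("2015-01-01")) / 365.25
dd <- predict_endpoint_egfr(base_egfr[di], pred[di], years,
                            last$egfr[li])
dd_mic <- predict_endpoint_egfr(base_egfr[di], pred_mic[di], years,
                                last$egfr[li])
cat(sprintf("endpoint eGFR RMSE: combined %.1f, MIC %.1f (n=%d)\n",
            rmse(last$egfr[li], dd$predicted_endpoint),
            rmse(last$egfr[li], dd_mic$predicted_endpoint), length(ids)))

# rapid-progressor discrimination (observed decline > 3 units/year)
roc_c <- roc_auc(pred, obs, cutoff = -3)
roc_m <- roc_auc(pred_mic, obs, cutoff = -3)
cat(sprintf("rapid-progressor AUC: combined %.2f, MIC %.2f\n",
            roc_c$auc, roc_m$auc))

# repeatability across time points (temporal cohort, same model)
Xt <- read_matrix("temporal")
pat_of_run <- sub("_T2$", "", rownames(Xt))
clin_t <- clin[match(pat_of_run, clin$patient_id), ]
ok <- !is.na(clin_t$patient_id) &
  !apply(is.na(Xt[, spec$proteins, drop = FALSE]), 1, any)
clin_t2 <- clin_t[ok, ]
clin_t2$patient_id <- rownames(Xt)[ok]   # one row per sample
des_t <- build_design(clin_t2, Xt, spec, scaling = des$scaling)
pred_t <- predict(fit, des_t$design)
rep_res <- repeatability(data.frame(patient_id = sub("_T2$", "",
                                                     des_t$patient_id),
                                    prediction = pred_t))
cat(sprintf("within-patient repeatability: %.0f%% of %d pairs within 1 unit\n",
            100 * rep_res$fraction_within, rep_res$n_pairs))

# serum-vs-plasma check on a hemolysis-style marker across cohorts
Xe <- read_matrix("external")
g <- intersect(colnames(X), colnames(Xe))[1]
mc <- marker_compare(X, Xe, g)
cat(sprintf("cross-cohort intensity check (%s): diff %.2f, p = %.2g\n",
            g, mc$mean_difference, mc$p))

report <- list(
  rmse_overall = list(combined = rmse(obs, pred), mic = rmse(obs, pred_mic)),
  agreement = ag[c("slope", "intercept", "slope_ci", "intercept_ci")],
  auc = list(combined = roc_c$auc, mic = roc_m$auc),
  repeatability = rep_res[c("fraction_within", "n_pairs")])
jsonlite::write_json(report, file.path(out, "evaluation_report.json"),
                     auto_unbox = TRUE, digits = NA)
cat("report written to", file.path(out, "evaluation_report.json"), "\n")
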