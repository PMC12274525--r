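#!/usr/bin/env Rscript
# Fit the progression models on the simulated screening cohort: the
# six-protein Proteome Model, the Clinical Model (age, sex, eGFR, Mayo
# class), their combination, and the refit Mayo-class comparator; repeated
# 2:1 train/test cross-validation of each. The transcribed published
# coefficient sets are evaluated at reference inputs alongside.

suppressPackageStartupMessages(library(pkdprog))

out <- "results/models"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

d <- read.table("results/matrix/screening_matrix.tsv", sep = "\t",
                header = TRUE, check.names = FALSE)
X <- as.matrix(`rownames<-`(d[, -1], d$sample))
slopes_df <- read.csv("results/slopes/screening_slopes.csv")
slopes_df <- slopes_df[slopes_df$included, ]
slopes <- setNames(slopes_df$slope_annual, slopes_df$patient_id)
clin <- read.csv("results/sim/screening/clinical.csv")
clin$egfr <- clin$baseline_egfr
clin$mayo_class <- mic_classify(clin$httkv_ml_per_m, clin$age)$mic_class
keep <- clin$patient_id %in% intersect(rownames(X), names(slopes))
clin <- clin[keep, ]

fits <- list()
for (spec_name in c("proteome", "clinical", "combined", "proteome4")) {
  spec <- model_spec(spec_name)
  des <- build_design(clin, X, spec, slopes = slopes)
  fit <- fit_linear_model(des$design, des$response, scaling = des$scaling)
  fits[[spec_name]] <- fit
  cv <- cross_validate(des$design, des$response, reps = 100,
                       seed = 20260925L)
  cat(sprintf("%-10s n=%d  R2=%.3f  adjR2=%.3f | CV: median R2=%.3f, mean RMSE=%.2f\n",
              spec_name, fit$n, fit$r2, fit$adj_r2, cv$median_r2,
              cv$mean_rmse))
  terms_out <- transform(fit$terms, beta = round(beta, 3),
                         ci_low = round(ci_low, 3),
                         ci_high = round(ci_high, 3), p = signif(p, 3))
  write.table(terms_out, file.path(out, paste0(spec_name, "_terms.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}

# Mayo-class comparator refit on this cohort
mic <- fit_mic_model(clin$mayo_class, slopes[clin$patient_id])
cat(sprintf("%-10s n=%d  R2=%.3f  adjR2=%.3f (class means: %s)\n",
            "mic", mic$n, mic$r2, mic$adj_r2,
            paste(sprintf("%s=%.2f", names(mic$class_means),
                          mic$class_means), collapse = ", ")))

# published worked examples (z-scored protein inputs, reference clinical)
pub <- published_models()
zeros <- as.list(setNames(rep(0, 6), model_spec("proteome")$proteins))
cat(sprintf("published proteome model at panel means: %.2f\n",
            evaluate_published(pub$proteome, zeros)))
saveRDS_path <- file.path(out, "fitted_models.json")
jsonlite::write_json(lapply(fits, function(f)
  list(n = f$n, r2 = f$r2, adj_r2 = f$adj_r2,
       terms = f$terms)), saveRDS_path, auto_unbox = TRUE, digits = NA)
cat("model fits written to", saveRDS_path, "\n")
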