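#!/usr/bin/env Rscript
# Univariate analyses on the screening cohort: moderated per-protein
# association with eGFR slope (FDR < 0.05), eGFR dependency of the
# associated proteins with cross-cohort sign concordance against the
# external cohort, detection-status association for the high-missingness
# marker, and 1-Pearson average-linkage clustering with cluster
# characteristics.

suppressPackageStartupMessages(library(pkdprog))

out <- "results/associations"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

read_matrix <- function(cohort) {
  d <- read.table(sprintf("results/matrix/%s_matrix.tsv", cohort),
                  sep = "\t", header = TRUE, check.names = FALSE)
  as.matrix(`rownames<-`(d[, -1], d$sample))
}
X <- read_matrix("screening")
slopes_df <- read.csv("results/slopes/screening_slopes.csv")
slopes_df <- slopes_df[slopes_df$included, ]
slopes <- setNames(slopes_df$slope_annual, slopes_df$patient_id)
common <- intersect(rownames(X), names(slopes))

assoc <- moderated_association(X[common, ], slopes)
assoc <- assoc[order(assoc$fdr), ]
write.table(assoc, file.path(out, "moderated_association.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
hits <- assoc$gene[assoc$fdr < 0.05]
cat(sprintf("moderated testing: %d of %d proteins at FDR < 0.05\n",
            length(hits), nrow(assoc)))
cat("  top hits:", paste(head(hits, 10), collapse = ", "), "\n")

# eGFR dependency of the hit panel, in screening and external cohorts
clin <- read.csv("results/sim/screening/clinical.csv")
egfr_s <- setNames(clin$baseline_egfr, clin$patient_id)
dep_s <- egfr_dependency(X[common, ], egfr_s, hits)
write.table(dep_s, file.path(out, "egfr_dependency_screening.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

Xe <- read_matrix("external")
clin_e <- read.csv("results/sim/external/clinical.csv")
egfr_e <- setNames(clin_e$baseline_egfr, clin_e$patient_id)
panel_e <- intersect(hits, colnames(Xe))
if (length(panel_e) > 0) {
  dep_e <- egfr_dependency(Xe, egfr_e, panel_e)
  conc <- sign_concordance(dep_s, dep_e)
  cat(sprintf("eGFR dependency: %d shared-significant proteins, %d sign-concordant\n",
              conc$n_shared, conc$n_concordant))
  write.table(dep_e, file.path(out, "egfr_dependency_external.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
}

# detection-status association for the high-missingness marker
mask <- read.table("results/matrix/screening_mask.tsv", sep = "\t",
                   header = TRUE, check.names = FALSE)
mask_m <- as.matrix(`rownames<-`(mask[, -1], mask$sample)) > 0
if ("RARRES2" %in% colnames(mask_m) &&
    length(unique(mask_m[common, "RARRES2"])) > 1) {
  det <- detection_association(mask_m[common, , drop = FALSE], slopes, "RARRES2")
  cat(sprintf("RARRES2 detection vs slope: r = %.3f, p = %.2g\n", det$r, det$p))
}

# clustering of the associated proteins and of patients
if (length(hits) >= 3) {
  cl_p <- hclust_corr(X[common, hits], axis = "proteins", k = 3)
  cl_s <- hclust_corr(X[common, hits], axis = "samples", k = 3,
                      sort_by = egfr_s)
  assign_df <- data.frame(patient_id = names(cl_s$assignment),
                          cluster = cl_s$assignment)
  write.table(assign_df, file.path(out, "patient_clusters.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  covars <- data.frame(age = clin$age, egfr = clin$baseline_egfr,
                       slope = slopes[clin$patient_id],
                       sex = factor(clin$sex),
                       row.names = clin$patient_id)
  covars <- covars[rownames(covars) %in% names(cl_s$assignment), ]
  # characteristic tests need >= 2 patients per cluster
  big <- names(table(cl_s$assignment))[table(cl_s$assignment) >= 2]
  keep_cl <- cl_s$assignment[cl_s$assignment %in% as.integer(big)]
  tests <- compare_clusters(keep_cl, covars[names(keep_cl), ])
  write.table(tests, file.path(out, "cluster_characteristics.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  sig <- tests[tests$p_adjusted < 0.05, ]
  cat(sprintf("patient clusters: %d; %d significant characteristic contrasts\n",
              max(cl_s$assignment), nrow(sig)))
}
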