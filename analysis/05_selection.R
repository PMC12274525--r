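#!/usr/bin/env Rscript
# Multivariate marker selection on the screening cohort: weighted-LASSO
# stability selection (100 resampled 2:1 splits, 10-fold CV lambda, >= 75%
# frequency rule) with Huber down-weighting of extreme slopes.

suppressPackageStartupMessages(library(pkdprog))

out <- "results/selection"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

d <- read.table("results/matrix/screening_matrix.tsv", sep = "\t",
                header = TRUE, check.names = FALSE)
X <- as.matrix(`rownames<-`(d[, -1], d$sample))
slopes_df <- read.csv("results/slopes/screening_slopes.csv")
slopes_df <- slopes_df[slopes_df$included, ]
slopes <- setNames(slopes_df$slope_annual, slopes_df$patient_id)
ids <- intersect(rownames(X), names(slopes))

sel <- stability_select(X[ids, ], slopes[ids],
                        stability_config(n_reps = 100, cv_folds = 10,
                                         threshold = 0.75, scheme = "huber",
                                         seed = 20260925L))
freq_df <- data.frame(gene = names(sel$frequency),
                      frequency = sel$frequency,
                      selected = names(sel$frequency) %in% sel$selected,
                      row.names = NULL)
write.table(freq_df, file.path(out, "selection_frequencies.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("stability selection on %d samples x %d proteins\n",
            length(ids), ncol(X)))
cat("selected (frequency >= 0.75):",
    paste(sel$selected, collapse = ", "), "\n")

# overlap with the univariate set, as reported in 04_associations
assoc <- read.table("results/associations/moderated_association.tsv",
                    sep = "\t", header = TRUE)
univ <- assoc$gene[assoc$fdr < 0.05]
cat(sprintf("overlap with the FDR < 0.05 set: %d proteins (%s)\n",
            length(intersect(sel$selected, univ)),
            paste(intersect(sel$selected, univ), collapse = ", ")))
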