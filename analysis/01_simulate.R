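#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a screening-style cohort (one serum
# sample per patient), a temporal validation cohort with follow-up samples,
# and an EDTA-plasma-like external cohort produced by a per-protein matrix
# shift. Writes plain-text inputs plus ground truth under results/sim/.

suppressPackageStartupMessages(library(pkdprog))

seed <- 20260925L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(n_patients = 200, seed = seed)
cohort <- generate_cohort(cfg)
prot_cfg <- proteome_sim_config(outlier_samples = 3, seed = seed)
proteome <- generate_proteome(cohort$ground_truth, prot_cfg)
write_cohort(cohort, proteome, dir = file.path(out, "screening"))

# temporal cohort: same patients, baseline + ~2y follow-up samples
proteome_t <- generate_proteome(cohort$ground_truth, prot_cfg,
                                followup_samples = TRUE)
write_cohort(cohort, proteome_t, dir = file.path(out, "temporal"))

# external cohort: fresh patients, plasma-like per-protein offsets
cfg_ext <- cohort_config(n_patients = 170, seed = seed + 1L)
cohort_ext <- generate_cohort(cfg_ext)
proteome_ext <- generate_proteome(cohort_ext$ground_truth,
                                  proteome_sim_config(seed = seed + 1L))
proteome_ext$report <- apply_cohort_shift(proteome_ext$report,
                                          prot_cfg$plasma_shift_sd,
                                          seed = seed + 1L)
write_cohort(cohort_ext, proteome_ext, dir = file.path(out, "external"))

cat("Simulated cohorts written under", out, "\n")
cat(sprintf("  screening: %d patients, %d report rows\n",
            nrow(cohort$clinical), nrow(proteome$report)))
cat(sprintf("  temporal:  %d samples\n", length(unique(proteome_t$report$Run))))
cat(sprintf("  external:  %d patients (plasma-shifted)\n",
            nrow(cohort_ext$clinical)))
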