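# pkdprog

Serum-proteomics prediction of kidney function decline in autosomal
dominant polycystic kidney disease (ADPKD).

ADPKD is the most common inherited cause of kidney failure, and the
decision to start disease-modifying therapy (tolvaptan) hinges on
predicting each patient's future rate of eGFR loss. The current clinical
standard, the Mayo Imaging Classification (MIC), needs MRI volumetry.
`pkdprog` implements, as a tested R pipeline, an analysis that predicts
the annual eGFR slope from serum DIA proteomics instead, and benchmarks
it against the MIC comparator. It is aimed at nephrology/proteomics
analysts who want to reproduce, probe, or extend this kind of
biomarker-to-model workflow.

## What the package computes

**Outcome — per-patient annualized eGFR slope.** eGFR from serum
creatinine via the 2009 CKD-EPI equation

    eGFR = 141 · min(Scr/κ, 1)^α · max(Scr/κ, 1)^(-1.209) · 0.993^age · 1.018[female]

(κ = 0.7/0.9 mg/dL, α = -0.329/-0.411 for women/men; no race term by
default). Measurements on/after the first intervention (tolvaptan,
dialysis, nephrectomy, transplant) are censored; each patient's slope is
a Huber robust fit eGFR = α + β·date (k = 1.345), with the per-day β
multiplied by 365.25. Patients enter analyses with ≥ 3 measurements and
slope in [-10, +5] mL/min/1.73 m²/yr.

**Predictors — DIA report to abundance matrix.** q ≤ 0.01 filter →
removal of proteins > 80% missing → per-sample variance-stabilizing
arsinh (glog) normalization → imputation from the dataset-wide 5th
percentile → PCA outlier flagging → empirical-Bayes (ComBat-style)
batch correction, with full provenance.

**Marker discovery.** Per-protein empirical-Bayes moderated association
with slope (BH FDR < 0.05) and weighted-LASSO stability selection: 100
seeded 2:1 splits, per-split 10-fold-CV λ, Huber down-weighted extreme
slopes, selection at ≥ 75% nonzero frequency.

**Models.** OLS progression models — Proteome (6 z-scored proteins:
SERPINF1, GPX3, AFM, FERMT3, CFHR1, RARRES2), Clinical (age, sex, eGFR,
Mayo class), Combined, genotype-extended and 4-protein variants — plus
the published screening-cohort coefficient sets shipped as data, and a
refit MIC class-mean comparator (r = ln(htTKV/150)/age, classes 1A-1E).

**Evaluation.** RMSE overall and by CKD stage, endpoint-eGFR prediction
(Δ = observed − predicted), robust agreement lines with bootstrap CIs,
within-patient repeatability, and rapid-progressor ROC/AUC (observed
decline > 3 units/yr).

Because the original registry data are not public, a synthetic cohort
generator (`generate_cohort()`, `generate_proteome()`) emulates the
study's statistical structure — demographics, linear noisy trajectories,
interventions, slope-linked marker effects, batches, left-censored
missingness — and exports ground truth so every stage is tested as a
recovery problem.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated 200-patient cohort (`Rscript analysis/01_simulate.R` …
`07_evaluation.R`). Highlights of one full run (seed 20260925):

```
$ Rscript analysis/02_slopes.R
screening: 200 patients, 127 measurements removed (37 patients), 194 slopes kept (6 excluded)

$ Rscript analysis/05_selection.R
stability selection on 191 samples x 200 proteins
selected (frequency >= 0.75): SERPINF1, AFM, FERMT3, CFHR1, RARRES2, GPX3

$ Rscript analysis/06_models.R
proteome   n=191  R2=0.479  adjR2=0.462 | CV: median R2=0.404, mean RMSE=1.98
clinical   n=191  R2=0.266  adjR2=0.246 | CV: median R2=0.195, mean RMSE=2.32
combined   n=191  R2=0.564  adjR2=0.537 | CV: median R2=0.476, mean RMSE=1.87

$ Rscript analysis/07_evaluation.R
slope RMSE (combined vs MIC): 1.74 vs 2.26 overall
rapid-progressor AUC: combined 0.87, MIC 0.77
```

Reading: censoring removed 127 intervention-affected measurements; all
six planted markers cleared the 75% stability threshold in this draw
(RARRES2, the 22%-missing marker, is routinely the most fragile — the
reason the 4-protein model variant exists); the combined
proteome+clinical model explains more slope variance than either part
and outperforms the imaging comparator on RMSE and rapid-progressor
discrimination. Across 10 generator seeds the acceptance suite requires
all six markers in ≥ 9 seeds.

Evaluating the shipped published models at reference inputs:

```r
library(pkdprog)
pm <- published_models()
evaluate_published(pm$proteome,
                   list(SERPINF1 = 0, GPX3 = 0, AFM = 0,
                        FERMT3 = 0, CFHR1 = 0, RARRES2 = 0))
#> [1] -2.74     # predicted slope, mL/min/1.73m2/yr, at panel means
```

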