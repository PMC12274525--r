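---
title: "Predicting eGFR decline in ADPKD from the serum proteome: methods"
author: "pkdprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting eGFR decline in ADPKD from the serum proteome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkdprog)
```

## The problem

Autosomal dominant polycystic kidney disease (ADPKD) progresses at very
different rates between patients, and therapeutic decisions — above all
whether to start tolvaptan — hinge on predicting each patient's future
rate of kidney function loss. The standard outcome measure is the annual
eGFR slope (mL/min/1.73 m² per year). The clinical gold standard for
prognosis, the Mayo Imaging Classification (MIC), requires MRI volumetry;
blood-borne markers would be far easier to obtain. `pkdprog` implements,
as a tested and reusable pipeline, an analysis that derives such markers
from serum DIA proteomics: per-patient robust eGFR slopes as the outcome,
a preprocessed protein abundance matrix as the predictor set, moderated
univariate screening plus weighted-LASSO stability selection to choose a
marker panel, and linear progression models benchmarked against a refit
MIC comparator.

The registry data behind the original analysis are not public, so the
package ships a synthetic cohort generator whose exported ground truth
turns every pipeline stage into a testable recovery problem. All numbers
below are computed by the package's tests and scripts, not quoted.

## The outcome: per-patient annualized eGFR slope

eGFR is computed from serum creatinine with the 2009 CKD-EPI creatinine
equation (constants in `ckd_epi_params()`; the race coefficient is
omitted by default — the emulated cohorts are European — but is
configurable through `race_factor`). Measurements on or after a patient's
first intervention (tolvaptan start, dialysis, nephrectomy, transplant)
are removed, because eGFR under these conditions no longer reflects the
untreated disease course; an intervention-day measurement counts as
affected. Each patient's slope is a Huber M-estimated linear fit of eGFR
on measurement date in days (tuning constant 1.345, at most 50 IRLS
iterations, tolerance 1e-8, ordinary least squares as fallback when IRLS
does not converge), with the per-day coefficient multiplied by 365.25.
Patients enter downstream analyses only with at least 3 retained
measurements and a slope inside [-10, +5] mL/min/1.73 m²/year. The
removal rule is read strictly ("greater than 5 or below -10"), so
boundary slopes are kept; and since visit dates enter as days, any
constant date shift leaves the slope unchanged (a tested invariant).

## The predictors: DIA report to abundance matrix

`preprocess_report()` chains the preprocessing stages in a fixed order,
with each step appended to a provenance log so a matrix can be
reproduced bit-for-bit under the same seeds:

1. **q-value filter** (`build_matrix`, q ≤ 0.01, inclusive): entries
   failing the identification threshold become missing values rather
   than deleted rows, so they count towards missingness.
2. **Missingness filter** (`filter_missing`): a protein is dropped iff
   strictly more than 80% of its values are missing (exactly 80% is
   kept).
3. **Variance-stabilizing normalization** (`vsn_normalize`): a
   per-sample affine-arsinh (generalized log) transform
   h_s(x) = arsinh(a_s + b_s·x), b_s > 0, calibrated by minimizing the
   profile negative log-likelihood — pooled within-protein residual
   variance penalized by the transform Jacobian — via BFGS with analytic
   gradients over all per-sample parameters jointly. Robustness comes
   from calibrating on the 90% least-variable proteins, re-selected over
   three outer rounds. Because each h_s is strictly monotone,
   within-sample rank order is preserved. On additive-plus-multiplicative
   noise the transform flattens the SD-versus-mean trend better than a
   plain log2 (a tested property).
4. **Left-censored imputation** (`impute_low`): each missing value is
   replaced by a draw, with replacement, from the observed values at or
   below the dataset-wide 5th percentile. The pool is dataset-wide, not
   per-protein — the literal reading of imputing "from the 5th
   percentile of the data" — which exaggerates how low a mid-abundance
   protein's missing values are imputed; the detection-status analysis
   (`detection_association`) exploits exactly this left-censoring
   structure.
5. **Outlier flagging** (`detect_outliers`): principal components of the
   centered/scaled matrix; a sample is flagged when its robust distance
   on the first two components (median/MAD standardized) exceeds
   `k_mad` = 5. The original analysis removed outliers by visual PCA
   inspection, which is not reproducible; the explicit threshold replaces
   it, and removal is a separate, logged action (`drop_samples`).
6. **Batch correction** (`combat_correct`): parametric empirical-Bayes
   location/scale adjustment — per-protein standardization, per-batch
   additive (γ) and multiplicative (δ²) effects shrunk towards
   moment-fitted normal and inverse-gamma priors by the standard
   iterative scheme, then back-transformation. A single batch is a no-op;
   singleton batches are an error. The implementation is authored here
   and agrees with the reference ComBat implementation to numerical
   tolerance on shared inputs (a cross-check test).

Screening-style and validation-style matrices are preprocessed
separately and intersected on gene names, mirroring how separately
acquired cohorts must be handled.

## Univariate screening and multivariate selection

`moderated_association()` fits, per protein, abundance on slope and
moderates residual variances by empirical Bayes (prior df and variance
estimated by moment-matching of log residual variances to a scaled F;
the computation is delegated to limma's lmFit/eBayes, and the shrinkage
formula s̃² = (d₀s₀² + d·s²)/(d₀ + d) is also exposed directly as
`posterior_var()` and cross-checked). Discovery is controlled at
Benjamini-Hochberg FDR < 0.05. With all simulated effects at zero, the
mean number of discoveries over 20 generator seeds stays below 2 of 200
proteins (an acceptance-tested calibration).

`stability_select()` implements the weighted-LASSO procedure: 100 seeded
2:1 train/test splits; on each training part an L1-penalized weighted
least-squares fit over a 100-point log-spaced λ grid (from the all-zero
λ down to 10⁻³ of it), λ chosen by 10-fold cross-validation of the
weighted test error with ties broken towards the sparser λ; a protein is
selected when its nonzero frequency reaches at least 75%. The
observation weights are the largest interpretive decision in the
package: the original description says only that the procedure was
tailored to mitigate the influence of extreme slope values. The default
`slope_weights(..., scheme = "huber")` standardizes slopes by
median/MAD and down-weights beyond the Huber constant k = 1.345
(w = k/|u|); `uniform` and user-supplied weights are provided as
alternatives, and test halves of the splits are used only for optional
error reporting, never for selection. No random-effect term is included
for the repeated-sample cohort: the source description does not
operationalize "controlling for patient variability", so the package
selects on one sample per patient by default rather than guessing a
model.

## Progression models

`build_design()` codes the model terms: protein abundances z-scored
(with the scaling stored, so models can be applied to new cohorts on the
training scale), sex as male = 1, Mayo class as dummies for 1C and for
pooled 1D-1E against a pooled 1A-1B reference — the only coding
consistent with the published coefficient rows — and genotype as
PKD1-truncating / PKD1-non-truncating dummies against PKD2. Models are
ordinary least squares with Wald t CIs and two-sided p-values
(`fit_linear_model`), validated by 100 seeded 2:1 train/test splits
(`cross_validate`; summaries are the median test R² and mean test
RMSE).

The published screening-cohort coefficient sets (proteome, clinical,
combined) ship as transcribed data (`published_models()`), and
`evaluate_published()` computes the linear predictor on the training
scale; protein inputs whose magnitude exceeds a plausibility bound are
rejected as presumably unstandardized. Protein predictors are assumed
z-scored in the published sets: their coefficient magnitudes (0.3-0.7
slope units) only make sense on a standardized scale while age and eGFR
are clearly in natural units. The four-protein variant
(`model_spec("proteome4")`) drops RARRES2 and FERMT3, the two markers
with high missingness in validation cohorts.

The MIC comparator (`mic_classify`, `fit_mic_model`) assigns classes
from the theoretical growth rate r = ln(htTKV/150)/age with half-open
boundaries at 1.5, 3, 4.5 and 6%/year, and predicts the class-mean
slope refit on the cohort at hand. Refitting (rather than transcribing
external class equations) matches how the comparator was actually used;
a class at exactly a boundary belongs to the higher class.

## Evaluation

`rmse_by_stage()` stratifies prediction error by CKD stage (default
stage 1 versus stages 2-4 pooled); the observation-weighted mean of the
group MSEs reproduces the overall MSE exactly (tested). Endpoint
prediction (`predict_endpoint_egfr`) projects baseline eGFR forward with
the predicted slope; Δ = observed − predicted, so positive values mean
over-predicted loss. Agreement between observed and predicted slopes is
summarized by a Huber robust regression line with case-resampling
percentile bootstrap 95% CIs (1000 replicates by default).
Repeatability across sampling time points uses all unordered
within-patient prediction pairs — not only consecutive ones — and
reports the fraction within one annual eGFR unit. Rapid-progressor
discrimination (`roc_auc`) labels observed decline strictly steeper than
3 units/year as rapid and ranks patients by the continuous predicted
slope (more negative = more likely rapid); AUC equals the Mann-Whitney
probability of correct ranking (tested against the brute-force count).

## The synthetic cohort generator

`generate_cohort()` draws ~57% female patients, age N(46, 12) truncated
to 18-80, baseline eGFR uniform on 30-110 (median near 70), true slopes
N(-2.7, 2.5) — centered on the intercept of the published proteome
model, with an SD placing most patients in the plausible -10..+5
range — and per-patient follow-up uniform on 0.6-1.4 times a median of
6.8 years. Visits are annual with ±30-day jitter (medical-record data
have no standardized time points); creatinine is obtained from the true
eGFR trajectory via the closed-form inverse CKD-EPI map times
multiplicative log-normal noise with 5% CV, a typical assay
coefficient of variation. Interventions hit each patient with fixed
probabilities (tolvaptan 0.2, others 1-2%) at a uniform time after year
one. Height-adjusted TKV is generated so that the implied Mayo class
correlates with the true slope but spreads over 1B-1D with 1C most
common, as in registry cohorts.

`generate_proteome()` builds log-intensities as protein baseline +
marker effect × standardized true slope + eGFR effect × standardized
eGFR + batch shift + batch-scaled noise, reported exponentiated with
simulated identification q-values. The six designated markers carry
effects of 0.5 residual SDs per slope SD with the published signs
(SERPINF1, FERMT3, CFHR1, RARRES2 negative; GPX3, AFM positive); a
cystatin-like CST3 has a strong negative eGFR dependence and GPX3 a
modest positive one. Missingness is left-censored: a global detection
limit at the 1st percentile of all log intensities (with identification
confidence degrading near it), plus per-protein censoring for designated
high-missingness proteins — RARRES2 at 22.2%. Effect sizes are
calibrated only to reproduce qualitative behavior (signs, missingness
rates, recoverability), not published coefficient magnitudes: no
generative model for protein-slope effects is available to transcribe.

What the generator does **not** emulate: non-linear eGFR trajectories,
assay drift within batches, correlated protein modules beyond the shared
slope/eGFR factors, peptide-level quantification artifacts, and
tolvaptan pharmacodynamics (interventions censor data; they do not bend
trajectories). Passing recovery tests therefore shows the pipeline is
correct and well-calibrated under its own assumptions — linear
trajectories, additive log-scale effects, MNAR left-censoring — not that
the published biological findings replicate.

## Numerical choices and degenerate inputs

* Problem sizes in tests and scripts: 200 patients × 200 proteins for
  recovery and calibration suites, 10 generator seeds for marker
  recovery and 20 for null calibration; chosen as the smallest sizes at
  which the selection procedure's behavior is stable across seeds.
* λ-grid anchoring takes the entry λ from the penalized-fit library
  itself so the all-zero property holds exactly under its weighting
  conventions.
* Dendrogram and λ ties break deterministically (lowest index / largest
  λ).
* `fit_patient_slope` requires ≥ 2 points and non-constant dates;
  `pearson_with_pvalue` requires ≥ 3 complete pairs and non-constant
  input; `impute_low` refuses a low pool of fewer than 10 values;
  `combat_correct` refuses singleton batches and no-ops on one batch;
  rank-deficient model designs are an error naming the collinear terms
  (the fate of a cystatin-like predictor collinear with the panel).
* All stochastic steps (generation, imputation, fold assignment, split
  resampling, bootstrap) are seeded explicitly; reruns are bit-for-bit
  reproducible.

## Known limitations

* The weight scheme of the weighted LASSO is an interpretation (Huber
  down-weighting), not a transcription; selection frequencies under
  alternative schemes can differ for borderline proteins.
* The vsn-style calibration is a re-implementation of the
  arsinh/profile-likelihood idea and matches the reference algorithm's
  behavior qualitatively (rank preservation, offset absorption, variance
  flattening), not coefficient-for-coefficient.
* Published-model evaluation requires z-scored protein inputs; applying
  them to a new cohort needs that cohort's own scaling, which is exactly
  how the stored-scaling mechanism in `build_design()` is intended to be
  used.
* With 0.5-SD effects, one of the six markers occasionally falls just
  short of the 75% selection frequency in an unlucky cohort draw; the
  recovery guarantee is therefore stated (and tested) across seeds, not
  per seed.
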