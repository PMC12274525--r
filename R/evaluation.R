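#' Root mean square error
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (length(observed) < 1) stop("empty input", call. = FALSE)
  sqrt(mean((observed - predicted)^2))
}

#' RMSE stratified by CKD stage group
#'
#' Stages are computed from baseline eGFR; the default grouping contrasts
#' stage 1 with stages 2-4 pooled. Empty groups are omitted from the
#' table.
#'
#' @param observed,predicted Slope vectors.
#' @param baseline_egfr Baseline eGFR per patient (same length).
#' @param grouping Named list of stage vectors.
#' @return Data frame: `group`, `n`, `rmse`.
#' @export
rmse_by_stage <- function(observed, predicted, baseline_egfr,
                          grouping = list("1" = 1, "2-4" = 2:4)) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(baseline_egfr))
  stage <- ckd_stage(baseline_egfr)
  rows <- lapply(names(grouping), function(g) {
    idx <- stage %in% grouping[[g]]
    if (!any(idx)) return(NULL)
    data.frame(group = g, n = sum(idx),
               rmse = rmse(observed[idx], predicted[idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Endpoint eGFR prediction error
#'
#' Projects each patient's baseline eGFR forward with the model-predicted
#' slope and compares to the last observed eGFR:
#' `delta = observed - (baseline + slope * years)`. Positive delta means
#' the model over-estimated eGFR loss.
#'
#' @param baseline_egfr Baseline eGFR.
#' @param predicted_slope Predicted annual slope.
#' @param elapsed_years Years from baseline to the last observation
#'   (non-negative).
#' @param observed_last_egfr Last observed eGFR.
#' @return Data frame: `predicted_endpoint`, `delta_egfr`.
#' @export
predict_endpoint_egfr <- function(baseline_egfr, predicted_slope,
                                  elapsed_years, observed_last_egfr) {
  if (any(elapsed_years < 0)) stop("elapsed_years must be >= 0", call. = FALSE)
  pred <- baseline_egfr + predicted_slope * elapsed_years
  data.frame(predicted_endpoint = pred,
             delta_egfr = observed_last_egfr - pred)
}

#' Robust observed-vs-predicted agreement line with bootstrap CI
#'
#' Huber robust regression (tuning constant 1.345) of observed on
#' predicted values, with case-resampling percentile bootstrap 95% CIs on
#' slope and intercept. A perfectly calibrated model gives slope 1,
#' intercept 0.
#'
#' @param observed,predicted Numeric vectors.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return List: `slope`, `intercept`, `slope_ci`, `intercept_ci`.
#' @export
agreement_line <- function(observed, predicted, n_boot = 1000, seed = 1L) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n < 3) stop("need >= 3 points", call. = FALSE)
  if (stats::sd(predicted) == 0) stop("constant predictions", call. = FALSE)
  fit_one <- function(obs, pred) {
    f <- suppressWarnings(MASS::rlm(obs ~ pred, k = 1.345, maxit = 50))
    stats::coef(f)
  }
  co <- fit_one(observed, predicted)
  set.seed(as.integer(seed))
  boots <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    idx <- sample(n, n, replace = TRUE)
    if (stats::sd(predicted[idx]) == 0) next
    boots[b, ] <- tryCatch(fit_one(observed[idx], predicted[idx]),
                           error = function(e) c(NA_real_, NA_real_))
  }
  ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       slope_ci = unname(ci[, 2]), intercept_ci = unname(ci[, 1]))
}

#' Within-patient repeatability of slope predictions
#'
#' For every patient sampled at multiple time points, evaluates all
#' unordered pairs of predictions and reports the fraction whose absolute
#' difference is at most one annual eGFR unit.
#'
#' @param predictions Data frame with `patient_id` and `prediction`
#'   (one row per sample).
#' @param within Tolerance (default 1 mL/min/1.73 m^2 per year).
#' @return List: `fraction_within`, `n_pairs`, `pair_diffs`.
#' @export
repeatability <- function(predictions, within = 1) {
  stopifnot(all(c("patient_id", "prediction") %in% names(predictions)))
  diffs <- numeric(0)
  for (id in unique(predictions$patient_id)) {
    p <- predictions$prediction[predictions$patient_id == id]
    if (length(p) >= 2) {
      diffs <- c(diffs, abs(utils::combn(p, 2, diff)))
    }
  }
  if (length(diffs) == 0) stop("no patients with >= 2 time points", call. = FALSE)
  list(fraction_within = mean(diffs <= within), n_pairs = length(diffs),
       pair_diffs = diffs)
}

#' ROC curve and AUC for rapid-progressor discrimination
#'
#' Labels patients as rapid progressors when the observed annual slope
#' falls strictly below the cutoff (default -3, the clinically used
#' decline of more than 3 mL/min/1.73 m^2 per year) and evaluates how well
#' the continuous predicted slope ranks them (more negative prediction =
#' more likely rapid). AUC is computed by pROC and equals the Mann-Whitney
#' probability of correct ranking.
#'
#' @param predicted_slopes Continuous model predictions.
#' @param observed_slopes Observed slopes used for labeling.
#' @param cutoff Labeling cutoff on the observed slope.
#' @return List of class `roc_result`: `auc`, `thresholds`,
#'   `sensitivity`, `specificity`, `labels`.
#' @export
roc_auc <- function(predicted_slopes, observed_slopes, cutoff = -3) {
  stopifnot(length(predicted_slopes) == length(observed_slopes))
  rapid <- observed_slopes < cutoff
  if (length(unique(rapid)) < 2) {
    stop("both rapid and stable progressors required after labeling",
         call. = FALSE)
  }
  r <- pROC::roc(response = rapid, predictor = predicted_slopes,
                 levels = c(FALSE, TRUE), direction = ">", quiet = TRUE)
  structure(list(auc = as.numeric(pROC::auc(r)),
                 thresholds = r$thresholds,
                 sensitivity = r$sensitivities,
                 specificity = r$specificities,
                 labels = rapid),
            class = "roc_result")
}

#' Cross-cohort intensity comparison for one protein
#'
#' Welch two-sample t-test on the (transformed) intensities of a gene in
#' two cohort matrices — e.g. checking a hemolysis marker (HBB) for
#' serum-vs-plasma differences.
#'
#' @param matrixA,matrixB `proteome_matrix` objects or plain matrices.
#' @param gene Gene (column) name present in both.
#' @return List: `mean_difference` (A - B), `p`, `t`, `n_a`, `n_b`.
#' @export
marker_compare <- function(matrixA, matrixB, gene) {
  XA <- if (inherits(matrixA, "proteome_matrix")) matrixA$values else matrixA
  XB <- if (inherits(matrixB, "proteome_matrix")) matrixB$values else matrixB
  if (!gene %in% colnames(XA) || !gene %in% colnames(XB)) {
    stop("gene absent from one of the matrices: ", gene, call. = FALSE)
  }
  a <- XA[, gene]; b <- XB[, gene]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("need >= 2 observations per cohort", call. = FALSE)
  }
  tt <- stats::t.test(a, b)
  list(mean_difference = mean(a) - mean(b), p = tt$p.value,
       t = unname(tt$statistic), n_a = length(a), n_b = length(b))
}
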