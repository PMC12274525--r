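#' Observation weights for the weighted LASSO
#'
#' Down-weights patients with extreme annual eGFR slopes so that they do
#' not dominate feature selection. The default Huber scheme standardizes
#' slopes by median/MAD and assigns weight 1 inside the tuning constant k
#' and k/|u| outside it.
#'
#' @param slopes Numeric vector of annual slopes.
#' @param scheme `"huber"`, `"uniform"`, or a numeric vector of custom
#'   weights (recycled check: must match length).
#' @param k Huber tuning constant.
#' @return Numeric weight vector in (0, 1].
#' @export
slope_weights <- function(slopes, scheme = c("huber", "uniform"), k = 1.345) {
  if (is.numeric(scheme)) {
    if (length(scheme) != length(slopes)) stop("custom weights length mismatch", call. = FALSE)
    return(scheme)
  }
  scheme <- match.arg(scheme)
  if (scheme == "uniform") return(rep(1, length(slopes)))
  s <- stats::mad(slopes)
  if (s == 0) stop("MAD of slopes is zero; huber weights undefined", call. = FALSE)
  u <- abs(slopes - stats::median(slopes)) / s
  ifelse(u <= k, 1, k / u)
}

lambda_grid <- function(X, y, w, n_lambda = 100, ratio = 1e-3) {
  # anchor at glmnet's entry lambda (the smallest that zeroes every
  # coefficient under its weighting/standardization conventions)
  f <- glmnet::glmnet(X, y, weights = w, nlambda = 3, standardize = TRUE,
                      family = "gaussian")
  lmax <- f$lambda[1]
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Weighted LASSO with 10-fold cross-validated lambda
#'
#' Minimizes the weighted squared loss plus an L1 penalty over a 100-point
#' log-spaced lambda grid (from the all-zero lambda down to 1e-3 of it);
#' lambda is chosen by k-fold cross-validation of the weighted test error,
#' ties broken towards the largest (sparsest) lambda. Predictors are
#' z-scored internally. Fitting is delegated to glmnet.
#'
#' @param X Numeric predictor matrix (samples x proteins).
#' @param y Response vector (annual slopes).
#' @param w Observation weights (default uniform).
#' @param folds Number of CV folds.
#' @param lambda Optional explicit lambda grid.
#' @param seed Seed for the fold assignment.
#' @return List: `lambda_opt`, `coefficients` (named, excluding intercept),
#'   `intercept`, `cv_error` (per-lambda mean weighted CV error),
#'   `lambda`, `nonzero` (names of nonzero coefficients).
#' @export
weighted_lasso_cv <- function(X, y, w = rep(1, length(y)), folds = 10,
                              lambda = NULL, seed = 1L) {
  stopifnot(nrow(X) == length(y), length(w) == length(y))
  n <- nrow(X)
  if (folds < 2 || folds > n) stop("invalid fold count", call. = FALSE)
  if (is.null(lambda)) lambda <- lambda_grid(X, y, w)

  set.seed(as.integer(seed))
  fold_id <- sample(rep_len(seq_len(folds), n))
  cv_err <- matrix(NA_real_, folds, length(lambda))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(tr) < 2 || sum(!tr) < 1) stop("degenerate fold", call. = FALSE)
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], weights = w[tr],
                          lambda = lambda, standardize = TRUE,
                          family = "gaussian")
    pred <- stats::predict(fit, newx = X[!tr, , drop = FALSE], s = lambda,
                           exact = FALSE)
    wte <- w[!tr]
    cv_err[f, ] <- colSums(wte * (y[!tr] - pred)^2) / sum(wte)
  }
  mean_err <- colMeans(cv_err)
  # ties (within numerical fuzz) -> largest lambda; grid is descending
  best <- which(mean_err <= min(mean_err) * (1 + 1e-10))[1]
  lambda_opt <- lambda[best]

  full <- glmnet::glmnet(X, y, weights = w, lambda = lambda,
                         standardize = TRUE, family = "gaussian")
  co <- stats::coef(full, s = lambda_opt, exact = FALSE)
  beta <- stats::setNames(as.numeric(co)[-1], rownames(co)[-1])
  list(lambda_opt = lambda_opt, coefficients = beta,
       intercept = as.numeric(co)[1], cv_error = mean_err, lambda = lambda,
       nonzero = names(beta)[beta != 0])
}

#' Stability-selection configuration
#'
#' @param n_reps Number of resampled train/test splits.
#' @param train_fraction Fraction of samples in each training split (2:1
#'   split = 2/3).
#' @param cv_folds CV folds for per-split lambda optimization.
#' @param threshold Selection-frequency threshold.
#' @param scheme Weight scheme passed to [slope_weights()].
#' @param k Huber tuning constant.
#' @param seed Integer seed.
#' @return List of class `stability_config`.
#' @export
stability_config <- function(n_reps = 100, train_fraction = 2 / 3,
                             cv_folds = 10, threshold = 0.75,
                             scheme = "huber", k = 1.345, seed = 1L) {
  stopifnot(threshold > 0, threshold <= 1, cv_folds >= 2, n_reps >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(n_reps = n_reps, train_fraction = train_fraction,
                 cv_folds = cv_folds, threshold = threshold,
                 scheme = scheme, k = k, seed = as.integer(seed)),
            class = "stability_config")
}

#' Weighted-LASSO stability selection of slope-associated proteins
#'
#' Repeats `n_reps` seeded 2:1 train/test splits; on each training part
#' fits the weighted LASSO with per-split 10-fold CV lambda optimization
#' and records the nonzero coefficient set. A protein is selected if its
#' nonzero frequency across splits reaches the threshold (default at least
#' 75% of the models). Weights are recomputed on each training split.
#'
#' @param X Predictor matrix (samples x proteins).
#' @param y Annual slopes.
#' @param config A [stability_config()].
#' @return List of class `selection_result`: `frequency` (named, sorted
#'   decreasing), `selected`, `lambda_opt` (per rep), `nonzero_sets`
#'   (per rep), `config`.
#' @export
stability_select <- function(X, y, config = stability_config()) {
  stopifnot(nrow(X) == length(y))
  n <- nrow(X)
  if (n < 15) stop("need >= 15 samples for a 2:1 split with 10-fold CV", call. = FALSE)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$n_reps)

  counts <- stats::setNames(numeric(ncol(X)), colnames(X))
  lambda_opt <- numeric(config$n_reps)
  nonzero_sets <- vector("list", config$n_reps)
  for (r in seq_len(config$n_reps)) {
    set.seed(rep_seeds[r])
    tr <- sample(n, floor(n * config$train_fraction))
    w <- slope_weights(y[tr], scheme = config$scheme, k = config$k)
    fit <- weighted_lasso_cv(X[tr, , drop = FALSE], y[tr], w = w,
                             folds = config$cv_folds, seed = rep_seeds[r])
    lambda_opt[r] <- fit$lambda_opt
    nonzero_sets[[r]] <- fit$nonzero
    counts[fit$nonzero] <- counts[fit$nonzero] + 1
  }
  freq <- sort(counts / config$n_reps, decreasing = TRUE)
  structure(list(frequency = freq,
                 selected = names(freq)[freq >= config$threshold],
                 lambda_opt = lambda_opt, nonzero_sets = nonzero_sets,
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("stability selection: %d reps, threshold %.2f\n",
              x$config$n_reps, x$config$threshold))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  print(utils::head(round(x$frequency, 2), 10))
  invisible(x)
}
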