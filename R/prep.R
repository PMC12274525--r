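#' Read a long-format DIA protein-group report
#'
#' Expects the tab-separated report dialect with columns `Run`,
#' `Protein.Group`, `Genes`, `Q.Value`, `Intensity`. Duplicate
#' (run, protein group) rows are rejected.
#'
#' @param path Path to a TSV file.
#' @return Data frame of class `raw_proteome_table`.
#' @export
read_report <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  as_raw_report(raw)
}

#' Validate an in-memory DIA report table
#'
#' @param raw Data frame with the report columns.
#' @return The validated table, classed `raw_proteome_table`.
#' @export
as_raw_report <- function(raw) {
  required <- c("Run", "Protein.Group", "Genes", "Q.Value", "Intensity")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("report is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$Q.Value <- as.numeric(raw$Q.Value)
  raw$Intensity <- as.numeric(raw$Intensity)
  if (any(is.na(raw$Q.Value)) || any(is.na(raw$Intensity))) {
    stop("unparseable numeric values in Q.Value/Intensity", call. = FALSE)
  }
  if (any(raw$Q.Value < 0 | raw$Q.Value > 1)) {
    stop("Q.Value outside [0,1]", call. = FALSE)
  }
  key <- paste(raw$Run, raw$Protein.Group, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicated (Run, Protein.Group) pair: ",
         gsub("\r", " / ", dup), call. = FALSE)
  }
  class(raw) <- c("raw_proteome_table", "data.frame")
  raw
}

new_proteome_matrix <- function(values, mask, batch = NULL,
                                provenance = character(0), gene_map = NULL) {
  structure(list(values = values, mask = mask, batch = batch,
                 provenance = provenance, gene_map = gene_map),
            class = "proteome_matrix")
}

#' @export
print.proteome_matrix <- function(x, ...) {
  cat(sprintf("proteome_matrix: %d samples x %d proteins, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  cat("provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

add_provenance <- function(m, step) {
  m$provenance <- c(m$provenance, step)
  m
}

#' Pivot a DIA report into a samples-by-proteins intensity matrix
#'
#' Entries whose identification q-value exceeds `q_max` are set missing
#' rather than row-deleted, so they count towards downstream missingness.
#' Columns are named by gene; the protein-group id mapping is retained.
#'
#' @param raw A `raw_proteome_table`.
#' @param q_max Maximum q-value retained (inclusive).
#' @param batch Optional data frame (`Run`, `batch`) of acquisition batch
#'   labels.
#' @return A `proteome_matrix` of raw intensities (NA = missing).
#' @export
build_matrix <- function(raw, q_max = 0.01, batch = NULL) {
  if (nrow(raw) == 0) stop("empty report table", call. = FALSE)
  raw$Intensity[raw$Q.Value > q_max] <- NA_real_
  runs <- sort(unique(raw$Run))
  # keep protein-group order; name columns by gene (unique-ified)
  pg <- unique(raw[, c("Protein.Group", "Genes")])
  genes <- make.unique(pg$Genes)
  values <- matrix(NA_real_, length(runs), nrow(pg),
                   dimnames = list(runs, genes))
  ri <- match(raw$Run, runs)
  ci <- match(raw$Protein.Group, pg$Protein.Group)
  values[cbind(ri, ci)] <- raw$Intensity
  batch_vec <- NULL
  if (!is.null(batch)) {
    stopifnot(all(c("Run", "batch") %in% names(batch)))
    batch_vec <- batch$batch[match(runs, batch$Run)]
    names(batch_vec) <- runs
  }
  new_proteome_matrix(values, is.na(values), batch = batch_vec,
                      provenance = sprintf("build_matrix(q_max=%g)", q_max),
                      gene_map = stats::setNames(pg$Protein.Group, genes))
}

#' Drop proteins exceeding a missingness threshold
#'
#' A protein is removed iff its fraction of missing values is strictly
#' greater than `max_na` (a protein at exactly the threshold is kept).
#'
#' @param matrix A `proteome_matrix`.
#' @param max_na Maximum tolerated NA fraction (default 0.80).
#' @return Filtered `proteome_matrix`.
#' @export
filter_missing <- function(matrix, max_na = 0.80) {
  na_frac <- colMeans(is.na(matrix$values))
  keep <- na_frac <= max_na
  matrix$values <- matrix$values[, keep, drop = FALSE]
  matrix$mask <- matrix$mask[, keep, drop = FALSE]
  if (!is.null(matrix$gene_map)) matrix$gene_map <- matrix$gene_map[keep]
  add_provenance(matrix, sprintf("filter_missing(max_na=%g)", max_na))
}

arsinh <- function(x) log(x + sqrt(x^2 + 1))

# Profile negative log-likelihood of the affine-arsinh calibration over a
# fixed protein subset, and its analytic gradient. The offset is nearly
# flat in the likelihood when every calibration protein sits far above
# zero, so it is parameterized as the log offset at the sample minimum:
# u = exp(t1_s) + b_s (x - min x_s) > 0 over each sample's observed
# range, with t2 = log b. Protein means are profiled out; by the
# envelope theorem the gradient needs no d m/d par terms. Xc holds
# x - min x_s, samples in rows.
vsn_profile_nll <- function(par, Xc) {
  S <- nrow(Xc)
  u0 <- exp(par[seq_len(S)])
  b <- exp(par[S + seq_len(S)])
  U <- u0 + b * Xc         # recycles u0, b down columns
  H <- arsinh(U)
  m <- colMeans(H, na.rm = TRUE)
  R <- sweep(H, 2, m)
  N <- sum(!is.na(Xc))
  rss <- sum(R^2, na.rm = TRUE)
  jac <- sum(sweep(-0.5 * log1p(U^2), 1, log(b), "+"), na.rm = TRUE)
  (N / 2) * log(rss / N) - jac
}

vsn_profile_grad <- function(par, Xc) {
  S <- nrow(Xc)
  u0 <- exp(par[seq_len(S)])
  b <- exp(par[S + seq_len(S)])
  U <- u0 + b * Xc
  H <- arsinh(U)
  m <- colMeans(H, na.rm = TRUE)
  R <- sweep(H, 2, m)
  N <- sum(!is.na(Xc))
  rss <- sum(R^2, na.rm = TRUE)
  inv2 <- 1 / (1 + U^2)
  inv <- sqrt(inv2)
  n_obs <- rowSums(!is.na(Xc))
  # du/dt1 = u0, du/dt2 = b * Xc
  d1_rss <- rowSums(R * inv, na.rm = TRUE) * u0
  d2_rss <- rowSums(R * inv * Xc, na.rm = TRUE) * b
  d1_jac <- rowSums(-U * inv2, na.rm = TRUE) * u0
  d2_jac <- n_obs + rowSums(-U * Xc * inv2, na.rm = TRUE) * b
  c((N / rss) * d1_rss - d1_jac,
    (N / rss) * d2_rss - d2_jac)
}

#' Variance-stabilizing normalization of a proteome matrix
#'
#' Calibrates a per-sample affine-arsinh transform `h_s(x) = arsinh(a_s +
#' b_s x)` (a generalized-log transform) by minimizing the pooled
#' within-protein residual variance penalized by the transform Jacobian
#' (profile likelihood), using the 90% least-variable proteins as the
#' calibration subset for robustness. The transform is strictly monotone
#' per sample (b_s > 0), so within-sample ranks are preserved.
#'
#' @param matrix A `proteome_matrix` of raw (positive) intensities.
#' @param trim Fraction of least-variable proteins used for calibration.
#' @param outer Number of trimmed-subset reselection rounds.
#' @param maxit BFGS iteration budget per round.
#' @return List with `matrix` (transformed `proteome_matrix`) and `fit`
#'   (data frame of per-sample `a`, `b`; class `vsn_fit`).
#' @export
vsn_normalize <- function(matrix, trim = 0.9, outer = 3, maxit = 1000) {
  X <- matrix$values
  if (nrow(X) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(X <= 0, na.rm = TRUE)) stop("intensities must be positive", call. = FALSE)
  S <- nrow(X); G <- ncol(X)

  xmin <- apply(X, 1, min, na.rm = TRUE)
  Xc <- X - xmin                       # per-sample offset-to-minimum
  # init: pure log-like transform per sample (offset at min = b * min)
  b0 <- 1 / apply(X, 1, function(r) stats::median(r, na.rm = TRUE))
  par <- c(log(b0 * xmin), log(b0))

  transform_all <- function(par) {
    u0 <- exp(par[seq_len(S)])
    b <- exp(par[S + seq_len(S)])
    arsinh(u0 + b * Xc)
  }

  converged <- FALSE
  for (round in seq_len(outer)) {
    H <- transform_all(par)
    pvar <- apply(H, 2, stats::var, na.rm = TRUE)
    subset <- which(rank(pvar, ties.method = "first") <=
                      max(2, floor(trim * G)))
    opt <- stats::optim(par, vsn_profile_nll, vsn_profile_grad,
                        Xc = Xc[, subset, drop = FALSE], method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10))
    par <- opt$par
    converged <- opt$convergence == 0
  }
  if (!converged) {
    warning("vsn_normalize: BFGS calibration hit the iteration budget (",
            maxit, "); results may be slightly off optimum")
  }

  matrix$values <- transform_all(par)
  dimnames(matrix$values) <- dimnames(X)
  matrix <- add_provenance(matrix, "vsn_normalize")
  b_fit <- exp(par[S + seq_len(S)])
  fit <- data.frame(sample = rownames(X),
                    a = exp(par[seq_len(S)]) - b_fit * xmin,
                    b = b_fit,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(fit) <- c("vsn_fit", "data.frame")
  list(matrix = matrix, fit = fit)
}

#' Impute missing values from the low-intensity tail
#'
#' Replaces every missing entry by a draw (with replacement) from the pool
#' of observed transformed intensities at or below the dataset-wide 5th
#' percentile, reflecting left-censored (missing-not-at-random)
#' missingness of low-abundance proteins.
#'
#' @param matrix A transformed `proteome_matrix`.
#' @param percentile Upper percentile bound of the sampling pool.
#' @param seed Integer seed; imputation is deterministic given it.
#' @return Imputed `proteome_matrix` (the mask still records which entries
#'   were imputed).
#' @export
impute_low <- function(matrix, percentile = 5, seed = 1L) {
  X <- matrix$values
  miss <- is.na(X)
  if (!any(miss)) {
    return(add_provenance(matrix, sprintf("impute_low(percentile=%g,noop)", percentile)))
  }
  obs <- X[!miss]
  cutoff <- stats::quantile(obs, percentile / 100, names = FALSE)
  pool <- obs[obs <= cutoff]
  if (length(pool) < 10) {
    stop("low-intensity pool has fewer than 10 values; increase `percentile`",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  X[miss] <- sample(pool, sum(miss), replace = TRUE)
  matrix$values <- X
  matrix$mask <- miss
  add_provenance(matrix, sprintf("impute_low(percentile=%g,seed=%d)",
                                 percentile, as.integer(seed)))
}

#' Flag outlier samples by robust PCA distance
#'
#' Computes principal components of the centered and scaled matrix and
#' flags samples whose robust distance on the first two components
#' (per-component median/MAD standardization) exceeds `k_mad`. Flagged
#' samples are reported; removal is left to the caller, mirroring the
#' visual-PCA practice the threshold replaces.
#'
#' @param matrix A `proteome_matrix` (transformed; any remaining NAs are
#'   mean-imputed for the PCA only).
#' @param k_mad Distance threshold in MAD units.
#' @return Character vector of flagged sample ids (possibly empty), with
#'   attribute `distance` giving all robust distances.
#' @export
detect_outliers <- function(matrix, k_mad = 5) {
  X <- matrix$values
  if (nrow(X) < 3) stop("need >= 3 samples", call. = FALSE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) == 0) stop("constant matrix: no variable proteins", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE, rank. = 2)
  z <- apply(pc$x[, 1:2, drop = FALSE], 2, function(v) {
    s <- stats::mad(v)
    if (s == 0) s <- stats::sd(v)
    (v - stats::median(v)) / s
  })
  d <- sqrt(rowSums(z^2))
  flagged <- rownames(matrix$values)[d > k_mad]
  attr(flagged, "distance") <- stats::setNames(d, rownames(matrix$values))
  flagged
}

#' Remove samples from a proteome matrix
#'
#' @param matrix A `proteome_matrix`.
#' @param samples Sample ids to drop.
#' @return The reduced matrix, with provenance recorded.
#' @export
drop_samples <- function(matrix, samples) {
  keep <- !(rownames(matrix$values) %in% samples)
  matrix$values <- matrix$values[keep, , drop = FALSE]
  matrix$mask <- matrix$mask[keep, , drop = FALSE]
  if (!is.null(matrix$batch)) matrix$batch <- matrix$batch[keep]
  add_provenance(matrix, sprintf("drop_samples(n=%d)", sum(!keep)))
}

#' Empirical-Bayes batch effect correction (location and scale)
#'
#' Parametric empirical-Bayes adjustment of per-batch, per-protein additive
#' (gamma) and multiplicative (delta^2) effects: proteins are standardized,
#' batch effects estimated and shrunk towards priors fitted by the method
#' of moments (normal prior for gamma, inverse-gamma for delta^2, solved by
#' the standard iterative scheme), then the data are adjusted and
#' back-transformed. A single batch is a no-op.
#'
#' @param matrix A `proteome_matrix` with batch labels (or pass `batch`).
#' @param batch Optional batch label vector overriding `matrix$batch`.
#' @param conv Convergence tolerance of the EB iteration.
#' @return List with `matrix` (corrected) and `fit` (class `batch_fit`:
#'   per-batch gamma/delta2 matrices and prior parameters).
#' @export
combat_correct <- function(matrix, batch = NULL, conv = 1e-6) {
  if (is.null(batch)) batch <- matrix$batch
  if (is.null(batch)) stop("no batch labels available", call. = FALSE)
  X <- matrix$values                       # samples x proteins
  stopifnot(length(batch) == nrow(X))
  batch <- factor(batch)
  nb <- table(batch)
  if (nlevels(batch) == 1) {
    return(list(matrix = add_provenance(matrix, "combat_correct(single_batch_noop)"),
                fit = NULL))
  }
  if (any(nb < 2)) {
    stop("singleton batch(es): ", paste(names(nb)[nb < 2], collapse = ", "),
         call. = FALSE)
  }

  dat <- t(X)                              # proteins x samples
  G <- nrow(dat); N <- ncol(dat)
  levels_b <- levels(batch)
  B <- length(levels_b)
  idx <- lapply(levels_b, function(l) which(batch == l))

  batch_means <- sapply(idx, function(ii) rowMeans(dat[, ii, drop = FALSE], na.rm = TRUE))
  grand_mean <- as.vector(batch_means %*% (as.numeric(nb) / N))
  # pooled variance of residuals around the fitted per-batch means
  fitted <- batch_means[, as.integer(batch), drop = FALSE]
  var_pooled <- rowSums((dat - fitted)^2, na.rm = TRUE) /
    rowSums(!is.na(dat))
  var_pooled[var_pooled == 0] <- 1e-12
  s_data <- (dat - grand_mean) / sqrt(var_pooled)

  gamma_hat <- sapply(idx, function(ii) rowMeans(s_data[, ii, drop = FALSE], na.rm = TRUE))
  delta_hat <- sapply(idx, function(ii) apply(s_data[, ii, drop = FALSE], 1,
                                              stats::var, na.rm = TRUE))
  delta_hat[!is.finite(delta_hat) | delta_hat == 0] <- 1e-12

  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, stats::var)
  # inverse-gamma prior on delta^2 by method of moments
  a_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(B)) {
    ii <- idx[[b]]
    n_g <- rowSums(!is.na(s_data[, ii, drop = FALSE]))
    g_old <- gamma_hat[, b]; d_old <- delta_hat[, b]
    repeat {
      g_new <- (n_g * t2[b] * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (n_g * t2[b] + d_old)
      sum2 <- rowSums((s_data[, ii, drop = FALSE] - g_new)^2, na.rm = TRUE)
      d_new <- (0.5 * sum2 + b_prior[b]) / (n_g / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    gamma_star[, b] <- g_old
    delta_star[, b] <- d_old
  }

  adj <- s_data
  for (b in seq_len(B)) {
    ii <- idx[[b]]
    adj[, ii] <- (s_data[, ii, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta_star[, b])
  }
  corrected <- adj * sqrt(var_pooled) + grand_mean

  matrix$values <- t(corrected)
  matrix <- add_provenance(matrix, "combat_correct")
  fit <- structure(list(gamma = gamma_star, delta2 = delta_star,
                        gamma_bar = gamma_bar, t2 = t2,
                        a_prior = a_prior, b_prior = b_prior,
                        batch_levels = levels_b),
                   class = "batch_fit")
  list(matrix = matrix, fit = fit)
}

#' Run the full preprocessing pipeline on a DIA report
#'
#' Convenience wrapper chaining [build_matrix()], [filter_missing()],
#' [vsn_normalize()], [impute_low()], [detect_outliers()]/[drop_samples()]
#' and [combat_correct()] in the standard order.
#'
#' @param raw A `raw_proteome_table`.
#' @param batch Optional batch data frame (`Run`, `batch`).
#' @param q_max,max_na,percentile,k_mad,seed Step parameters.
#' @param remove_outliers If TRUE (default) flagged samples are dropped
#'   before batch correction.
#' @return List with `matrix`, `outliers`, `vsn_fit`, `batch_fit`.
#' @export
preprocess_report <- function(raw, batch = NULL, q_max = 0.01, max_na = 0.80,
                              percentile = 5, k_mad = 5, seed = 1L,
                              remove_outliers = TRUE) {
  m <- build_matrix(raw, q_max = q_max, batch = batch)
  m <- filter_missing(m, max_na = max_na)
  v <- vsn_normalize(m)
  m <- impute_low(v$matrix, percentile = percentile, seed = seed)
  outliers <- detect_outliers(m, k_mad = k_mad)
  if (remove_outliers && length(outliers) > 0) m <- drop_samples(m, outliers)
  bf <- NULL
  if (!is.null(m$batch) && length(unique(m$batch)) > 1) {
    cc <- combat_correct(m)
    m <- cc$matrix
    bf <- cc$fit
  }
  list(matrix = m, outliers = outliers, vsn_fit = v$fit, batch_fit = bf)
}
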