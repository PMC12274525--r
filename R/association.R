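#' Empirical-Bayes posterior residual variance
#'
#' The moderated-test shrinkage formula: `(d0*s0^2 + d_g*s_g^2)/(d0 + d_g)`,
#' pulling each protein's residual variance towards the prior.
#'
#' @param s2 Per-protein residual variance.
#' @param df Residual degrees of freedom.
#' @param d0 Prior degrees of freedom (may be Inf).
#' @param s02 Prior variance.
#' @return Posterior variance, between `min(s2, s02)` and `max(s2, s02)`.
#' @export
posterior_var <- function(s2, df, d0, s02) {
  if (is.infinite(d0)) return(rep(s02, length(s2)))
  (d0 * s02 + df * s2) / (d0 + df)
}

#' Moderated per-protein association with eGFR slope
#'
#' Fits, per protein, a linear model of transformed abundance on the
#' annual eGFR slope and moderates the residual variances by empirical
#' Bayes: the prior (d0, s0^2) is estimated by moment-matching of the log
#' residual variances to a scaled F distribution, and each protein's
#' t-statistic uses the posterior variance on d0 + d_g degrees of freedom.
#' P-values are Benjamini-Hochberg adjusted. Backed by limma's lmFit/eBayes
#' machinery.
#'
#' @param matrix A `proteome_matrix` (samples x proteins) or plain matrix.
#' @param slopes Named numeric vector of annual slopes, or data frame with
#'   `patient_id` and `slope_annual`; sample names must match matrix rows.
#' @return Data frame per protein: `gene`, `coef`, `s2`, `df`, `s2_post`,
#'   `t_mod`, `p`, `fdr`, plus attributes `d0` and `s02`.
#' @export
moderated_association <- function(matrix, slopes) {
  X <- if (inherits(matrix, "proteome_matrix")) matrix$values else matrix
  if (is.data.frame(slopes)) {
    slopes <- stats::setNames(slopes$slope_annual, slopes$patient_id)
  }
  if (is.null(names(slopes)) || is.null(rownames(X))) {
    stop("samples must be named in both matrix and slopes", call. = FALSE)
  }
  common <- intersect(rownames(X), names(slopes))
  if (length(common) < 3) stop("fewer than 3 aligned samples", call. = FALSE)
  X <- X[common, , drop = FALSE]
  y <- slopes[common]
  zero_var <- apply(X, 2, function(v) stats::var(v, na.rm = TRUE)) == 0
  if (any(zero_var)) {
    stop("zero-variance protein(s): ",
         paste(utils::head(colnames(X)[zero_var], 5), collapse = ", "),
         call. = FALSE)
  }

  design <- cbind(Intercept = 1, slope = y)
  fit <- limma::lmFit(t(X), design)
  fit <- limma::eBayes(fit)
  p <- fit$p.value[, "slope"]
  res <- data.frame(
    gene = colnames(X),
    coef = fit$coefficients[, "slope"],
    s2 = fit$sigma^2,
    df = fit$df.residual,
    s2_post = fit$s2.post,
    t_mod = fit$t[, "slope"],
    p = p,
    fdr = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- fit$df.prior
  attr(res, "s02") <- fit$s2.prior
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return Adjusted values (monotone step-up, capped at 1).
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Pearson correlation with t-based p-value
#'
#' Pairwise-complete Pearson correlation; the p-value is from
#' `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors (NAs dropped pairwise).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_pvalue <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' eGFR dependency of a protein panel
#'
#' Correlates each panel protein's abundance with the eGFR at the time of
#' biosampling, to distinguish slope-linked markers that also track current
#' kidney function from those that do not.
#'
#' @param matrix A `proteome_matrix` or plain matrix (samples x proteins).
#' @param egfr_at_sampling Named numeric vector of eGFR values.
#' @param protein_panel Character vector of panel proteins (must exist in
#'   the matrix).
#' @return Data frame: `gene`, `r`, `p`, `n`, `sign`.
#' @export
egfr_dependency <- function(matrix, egfr_at_sampling, protein_panel) {
  X <- if (inherits(matrix, "proteome_matrix")) matrix$values else matrix
  if (length(protein_panel) == 0) stop("empty protein panel", call. = FALSE)
  missing_p <- setdiff(protein_panel, colnames(X))
  if (length(missing_p) > 0) {
    stop("panel protein(s) absent from matrix: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  common <- intersect(rownames(X), names(egfr_at_sampling))
  rows <- lapply(protein_panel, function(g) {
    res <- pearson_with_pvalue(X[common, g], egfr_at_sampling[common])
    data.frame(gene = g, r = res$r, p = res$p, n = res$n,
               sign = sign(res$r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-cohort sign concordance of eGFR correlations
#'
#' Lists proteins significant in both cohorts' correlation tables at
#' `alpha` and whether their correlation signs agree.
#'
#' @param tableA,tableB Data frames from [egfr_dependency()].
#' @param alpha Significance threshold.
#' @return List: `shared_significant` (data frame with `gene`, `r_a`,
#'   `r_b`, `concordant`), `n_shared`, `n_concordant`.
#' @export
sign_concordance <- function(tableA, tableB, alpha = 0.05) {
  overlap <- intersect(tableA$gene, tableB$gene)
  if (length(overlap) == 0) stop("no overlapping proteins", call. = FALSE)
  a <- tableA[match(overlap, tableA$gene), ]
  b <- tableB[match(overlap, tableB$gene), ]
  sig <- a$p < alpha & b$p < alpha
  shared <- data.frame(gene = overlap[sig],
                       r_a = a$r[sig], r_b = b$r[sig],
                       concordant = sign(a$r[sig]) == sign(b$r[sig]),
                       stringsAsFactors = FALSE)
  list(shared_significant = shared,
       n_shared = nrow(shared),
       n_concordant = sum(shared$concordant))
}

#' Association between protein detection status and eGFR slope
#'
#' For a protein with substantial missingness, tests whether the binary
#' detected/undetected indicator itself correlates (point-biserial) with
#' the annual slope — informative when missingness is left-censored.
#'
#' @param raw_mask Logical matrix (samples x proteins), TRUE = missing, as
#'   stored in `proteome_matrix$mask`.
#' @param slopes Named numeric vector of slopes.
#' @param protein Protein (column) name.
#' @return List `r`, `p`, `n` for detected-indicator vs slope.
#' @export
detection_association <- function(raw_mask, slopes, protein) {
  if (!protein %in% colnames(raw_mask)) {
    stop("protein not in mask: ", protein, call. = FALSE)
  }
  common <- intersect(rownames(raw_mask), names(slopes))
  detected <- as.numeric(!raw_mask[common, protein])
  if (length(unique(detected)) < 2) {
    stop("protein is all-detected or all-undetected: ", protein, call. = FALSE)
  }
  pearson_with_pvalue(detected, slopes[common])
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Clusters proteins (columns) or samples (rows) using distance
#' `1 - Pearson correlation` and average linkage, cut into `k` clusters.
#' Sample clusters can be sorted by eGFR within cluster for display.
#'
#' @param matrix A `proteome_matrix` or plain matrix (samples x proteins).
#' @param axis `"proteins"` or `"samples"`.
#' @param k Number of clusters.
#' @param sort_by Optional named numeric vector (e.g. eGFR) used to order
#'   items within cluster (samples axis).
#' @return List of class `cluster_result`: `hclust` object, `assignment`
#'   (named integer vector), `order` (display order).
#' @export
hclust_corr <- function(matrix, axis = c("proteins", "samples"), k = 3,
                        sort_by = NULL) {
  X <- if (inherits(matrix, "proteome_matrix")) matrix$values else matrix
  axis <- match.arg(axis)
  M <- if (axis == "proteins") X else t(X)   # items in columns
  if (ncol(M) < k) stop("fewer items than k", call. = FALSE)
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0)) {
    stop("constant item(s): correlation undefined for ",
         paste(utils::head(colnames(M)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(M, use = "pairwise.complete.obs"))
  hc <- stats::hclust(d, method = "average")
  assignment <- stats::cutree(hc, k = k)
  ord <- hc$order
  if (!is.null(sort_by)) {
    items <- colnames(M)
    ord <- order(assignment[items], sort_by[items])
  }
  structure(list(hclust = hc, assignment = assignment, order = ord, k = k),
            class = "cluster_result")
}

#' Compare covariates across clusters
#'
#' Continuous covariates: all pairwise two-sided Welch t-tests between
#' clusters with Bonferroni adjustment. Categorical covariates: per-cluster
#' one-sample proportion test against the whole-cohort proportion.
#'
#' @param assignment Named cluster assignment (from [hclust_corr()]).
#' @param covariates Data frame, one row per item (rownames or `id` column
#'   matching assignment names); numeric columns treated as continuous,
#'   others as categorical.
#' @return Data frame: `covariate`, `comparison`, `statistic`, `p`,
#'   `p_adjusted`, `test`.
#' @export
compare_clusters <- function(assignment, covariates) {
  if (!is.null(covariates$id)) {
    rownames(covariates) <- covariates$id
    covariates$id <- NULL
  }
  items <- intersect(names(assignment), rownames(covariates))
  assignment <- assignment[items]
  covariates <- covariates[items, , drop = FALSE]
  cl <- sort(unique(assignment))
  if (length(cl) < 2) stop("need >= 2 clusters", call. = FALSE)

  out <- list()
  for (v in names(covariates)) {
    x <- covariates[[v]]
    if (is.numeric(x)) {
      pairs <- utils::combn(cl, 2, simplify = FALSE)
      praw <- numeric(0); stat <- numeric(0); lab <- character(0)
      for (pr in pairs) {
        xi <- x[assignment == pr[1]]; xj <- x[assignment == pr[2]]
        if (length(xi) < 2 || length(xj) < 2) {
          stop("cluster with < 2 items for t-test on ", v, call. = FALSE)
        }
        tt <- stats::t.test(xi, xj)
        praw <- c(praw, tt$p.value); stat <- c(stat, unname(tt$statistic))
        lab <- c(lab, paste(pr, collapse = " vs "))
      }
      out[[length(out) + 1]] <- data.frame(
        covariate = v, comparison = lab, statistic = stat, p = praw,
        p_adjusted = pmin(praw * length(praw), 1), test = "t",
        stringsAsFactors = FALSE)
    } else {
      x <- as.factor(x)
      ref_level <- levels(x)[1]
      p0 <- mean(x == ref_level)
      for (ci in cl) {
        xi <- x[assignment == ci]
        pt <- suppressWarnings(stats::prop.test(sum(xi == ref_level),
                                                length(xi), p = p0))
        out[[length(out) + 1]] <- data.frame(
          covariate = v,
          comparison = sprintf("cluster %s vs cohort (%s)", ci, ref_level),
          statistic = unname(pt$statistic), p = pt$p.value,
          p_adjusted = pt$p.value, test = "prop",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
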