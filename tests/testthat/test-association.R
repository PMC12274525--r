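test_that("posterior variance shrinkage follows the moderation formula", {
  expect_equal(posterior_var(4, 10, 4, 1), 44 / 14)
  expect_equal(posterior_var(4, 10, Inf, 1), 1)
  # always between the observed and prior variance
  set.seed(1)
  for (i in 1:20) {
    s2 <- runif(1, 0.1, 5); s02 <- runif(1, 0.1, 5)
    sp <- posterior_var(s2, 10, 4, s02)
    expect_gte(sp, min(s2, s02) - 1e-12)
    expect_lte(sp, max(s2, s02) + 1e-12)
  }
})

test_that("moderated association agrees with per-protein OLS coefficients", {
  m <- random_matrix(30, 20, seed = 2)
  set.seed(3)
  slopes <- setNames(rnorm(30, -2.7, 2), rownames(m$values))
  res <- moderated_association(m, slopes)
  expect_equal(nrow(res), 20)
  ols <- apply(m$values, 2, function(v) coef(lm(v ~ slopes))[2])
  expect_equal(res$coef, unname(ols), tolerance = 1e-10)
  # posterior variance consistent with the exposed formula
  expect_equal(res$s2_post,
               posterior_var(res$s2, res$df, attr(res, "d0"), attr(res, "s02")),
               tolerance = 1e-8)
  # misalignment and zero variance raise errors
  bad <- slopes; names(bad) <- paste0("X", seq_along(bad))
  expect_error(moderated_association(m, bad), "aligned")
  m2 <- m; m2$values[, 1] <- 5
  expect_error(moderated_association(m2, slopes), "zero-variance")
})

test_that("moderated testing is calibrated under the null", {
  coh <- generate_cohort(cohort_config(n_patients = 120, seed = 4))
  cfg <- proteome_sim_config(n_proteins = 120,
                             marker_effects = default_marker_effects(0),
                             egfr_effects = c(CST3 = 0), n_batches = 1,
                             seed = 4)
  pr <- generate_proteome(coh$ground_truth, cfg)
  m <- impute_low(vsn_normalize(filter_missing(
    build_matrix(as_raw_report(pr$report))))$matrix, seed = 4)
  slopes <- setNames(coh$ground_truth$patients$true_slope,
                     coh$ground_truth$patients$patient_id)
  res <- moderated_association(m, slopes)
  expect_lte(sum(res$fdr < 0.05), 2)
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj <= 1 & adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # discoveries are non-increasing as alpha tightens
  expect_lte(sum(adj < 0.01), sum(adj < 0.05))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("Pearson correlation with p-value matches the formula oracle", {
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 8.1, 9.7)
  res <- pearson_with_pvalue(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_oracle <- r_oracle * sqrt(3 / (1 - r_oracle^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 3), tolerance = 1e-12)
  expect_equal(res$n, 5)
  # perfect line, sign flip, NA pairs
  expect_equal(pearson_with_pvalue(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_pvalue(x, -y)$r, -res$r)
  expect_equal(pearson_with_pvalue(c(x, NA), c(y, 5))$n, 5)
  expect_error(pearson_with_pvalue(x, rep(1, 5)), "constant")
  expect_error(pearson_with_pvalue(1:2, 1:2), ">= 3")
})

test_that("eGFR dependency finds a cystatin-like protein", {
  coh <- generate_cohort(cohort_config(n_patients = 150, seed = 6))
  cfg <- proteome_sim_config(n_proteins = 30,
                             marker_effects = default_marker_effects(0),
                             egfr_effects = c(CST3 = -1), n_batches = 1,
                             seed = 6)
  pr <- generate_proteome(coh$ground_truth, cfg)
  m <- impute_low(vsn_normalize(filter_missing(
    build_matrix(as_raw_report(pr$report))))$matrix, seed = 6)
  egfr <- setNames(coh$ground_truth$patients$true_baseline_egfr,
                   coh$ground_truth$patients$patient_id)
  tab <- egfr_dependency(m, egfr, c("CST3", "G0010", "G0020"))
  expect_equal(nrow(tab), 3)
  cst <- tab[tab$gene == "CST3", ]
  expect_lt(cst$r, 0)
  expect_lt(cst$p, 0.001)
  null_p <- tab$p[tab$gene != "CST3"]
  expect_true(all(abs(tab$r[tab$gene != "CST3"]) < 0.5))
  expect_error(egfr_dependency(m, egfr, character(0)), "empty")
  expect_error(egfr_dependency(m, egfr, "NOPE"), "absent")
})

test_that("sign concordance summarizes shared significant proteins", {
  tab <- data.frame(gene = paste0("G", 1:10),
                    r = c(0.8, -0.7, 0.6, 0.5, -0.4, 0.1, 0.05, -0.2, 0.3, 0.9),
                    p = c(rep(0.001, 5), rep(0.5, 5)))
  same <- sign_concordance(tab, tab)
  expect_equal(same$n_shared, 5)
  expect_equal(same$n_concordant, 5)
  flip <- tab; flip$r <- -flip$r
  opp <- sign_concordance(tab, flip)
  expect_equal(opp$n_concordant, 0)
  expect_error(sign_concordance(tab, data.frame(gene = "ZZZ", r = 1, p = 1)),
               "overlap")
})

test_that("detection status correlates with slope for censored markers", {
  coh <- generate_cohort(cohort_config(n_patients = 200, seed = 7))
  cfg <- proteome_sim_config(n_proteins = 20,
                             marker_effects = c(RARRES2 = -1.5),
                             egfr_effects = c(CST3 = 0),
                             rarres2_like_missing_rate = 0.3,
                             missing_censor_quantile = 0,
                             global_detect_quantile = 0,
                             n_batches = 1, seed = 7)
  pr <- generate_proteome(coh$ground_truth, cfg)
  m <- build_matrix(as_raw_report(pr$report), q_max = 1)
  slopes <- setNames(coh$ground_truth$patients$true_slope,
                     coh$ground_truth$patients$patient_id)
  # RARRES2 rises with faster decline (negative slope effect), so
  # left-censoring hides it in slow progressors: detection correlates
  # negatively with slope
  res <- detection_association(m$mask, slopes, "RARRES2")
  expect_lt(res$r, 0)
  expect_lt(res$p, 0.05)
  expect_error(detection_association(m$mask, slopes, "CST3"), "all-detected")
})

test_that("correlation clustering matches a brute-force average-linkage oracle", {
  set.seed(8)
  X <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(sprintf("S%02d", 1:20), sprintf("G%d", 1:5)))
  d <- as.dist(1 - cor(X))
  res <- hclust_corr(X, axis = "proteins", k = 2)
  expect_equal(res$hclust$height, average_linkage_heights(d), tolerance = 1e-12)

  # identical proteins merge first at height 0
  X2 <- X; X2[, 2] <- X2[, 1]
  res2 <- hclust_corr(X2, axis = "proteins", k = 2)
  expect_equal(res2$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(res2$hclust$merge[1, ]), c(1, 2))

  # k clusters, all nonempty; permutation invariance of the partition
  res3 <- hclust_corr(X, axis = "proteins", k = 3)
  expect_equal(length(unique(res3$assignment)), 3)
  perm <- sample(5)
  res4 <- hclust_corr(X[, perm], axis = "proteins", k = 3)
  relabel <- function(a) match(a, unique(a))
  expect_identical(relabel(res3$assignment[colnames(X)[perm]]),
                   relabel(res4$assignment))
  expect_error(hclust_corr(cbind(X, G6 = 1), axis = "proteins", k = 2),
               "constant")
})

test_that("cluster characteristic tests detect a shifted cluster", {
  set.seed(9)
  assignment <- setNames(rep(1:3, each = 50), sprintf("S%03d", 1:150))
  cov <- data.frame(age = c(rnorm(50, 46, 5), rnorm(50, 56, 5), rnorm(50, 46, 5)),
                    sex = factor(rep(c("female", "male"), 75)),
                    row.names = names(assignment))
  tab <- compare_clusters(assignment, cov)
  t12 <- tab[tab$covariate == "age" & tab$comparison == "1 vs 2", ]
  expect_lt(t12$p_adjusted, 0.001)
  t13 <- tab[tab$covariate == "age" & tab$comparison == "1 vs 3", ]
  expect_gt(t13$p_adjusted, 0.05)
  # proportion test statistic equals the chi-square oracle
  p1 <- tab[tab$covariate == "sex" & grepl("cluster 1", tab$comparison), ]
  x <- sum(cov$sex[assignment == 1] == "female")
  oracle <- suppressWarnings(prop.test(x, 50, p = mean(cov$sex == "female")))
  expect_equal(p1$statistic, unname(oracle$statistic))
  expect_equal(p1$p, oracle$p.value)
})

test_that("paired cohorts sharing eGFR-dependent proteins are concordant", {
  eff <- setNames(rep(c(-0.9, 0.9), length.out = 9), paste0("DEP", 1:9))
  make_cohort <- function(seed) {
    coh <- generate_cohort(cohort_config(n_patients = 150, seed = seed))
    cfg <- proteome_sim_config(n_proteins = 40,
                               marker_effects = default_marker_effects(0),
                               egfr_effects = eff, n_batches = 1,
                               global_detect_quantile = 0, seed = seed)
    pr <- generate_proteome(coh$ground_truth, cfg)
    rep <- apply_cohort_shift(pr$report, 0.4, seed = seed)
    m <- impute_low(vsn_normalize(filter_missing(
      build_matrix(as_raw_report(rep))))$matrix, seed = seed)
    egfr <- setNames(coh$ground_truth$patients$true_baseline_egfr,
                     coh$ground_truth$patients$patient_id)
    egfr_dependency(m, egfr, names(eff))
  }
  depA <- make_cohort(21)
  depB <- make_cohort(22)
  conc <- sign_concordance(depA, depB, alpha = 0.05)
  expect_equal(conc$n_shared, 9)
  expect_equal(conc$n_concordant, 9)
})
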