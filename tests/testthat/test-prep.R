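test_that("report parsing validates columns, numerics and duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tiny_report(), path, sep = "\t", row.names = FALSE, quote = FALSE)
  raw <- read_report(path)
  expect_equal(nrow(raw), 4)
  expect_s3_class(raw, "raw_proteome_table")

  expect_error(as_raw_report(tiny_report()[, -4]), "Q.Value")
  dup <- rbind(tiny_report(), tiny_report()[1, ])
  expect_error(as_raw_report(dup), "duplicated.*S1.*PG1")
  bad <- tiny_report(); bad$Q.Value[1] <- 2
  expect_error(as_raw_report(bad), "\\[0,1\\]")
})

test_that("q-value filtering masks entries inclusively at the bound", {
  m <- build_matrix(as_raw_report(tiny_report()), q_max = 0.01)
  expect_true(is.na(m$values["S2", "GENEA"]))    # q = 0.02 > 0.01
  expect_false(is.na(m$values["S2", "GENEB"]))   # q = 0.01 retained
  expect_false(is.na(m$values["S1", "GENEA"]))
  # all entries pass at q_max = 1
  m2 <- build_matrix(as_raw_report(tiny_report()), q_max = 1)
  expect_equal(sum(is.na(m2$values)), 0)
  expect_error(build_matrix(as_raw_report(tiny_report()[0, ])), "empty")
})

test_that("missingness filter drops strictly above the threshold", {
  set.seed(1)
  X <- matrix(rnorm(10 * 4, 10), 10, 4,
              dimnames = list(sprintf("S%d", 1:10), sprintf("G%d", 1:4)))
  X[1:9, 1] <- NA          # 90% -> dropped
  X[1:8, 2] <- NA          # exactly 80% -> kept
  X[1:2, 3] <- NA          # 20% -> kept
  m <- pkdprog:::new_proteome_matrix(X, is.na(X))
  out <- filter_missing(m, max_na = 0.80)
  expect_setequal(colnames(out$values), c("G2", "G3", "G4"))

  # brute-force oracle on a random pattern
  set.seed(2)
  Y <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("S%d", 1:20), sprintf("G%d", 1:10)))
  Y[sample(length(Y), 120)] <- NA
  oracle <- sum(sapply(seq_len(10), function(j) mean(is.na(Y[, j])) <= 0.8))
  m2 <- filter_missing(pkdprog:::new_proteome_matrix(Y, is.na(Y)))
  expect_equal(ncol(m2$values), oracle)
})

test_that("vsn calibration restores scale shifts and preserves ranks", {
  set.seed(2)
  base <- matrix(exp(rnorm(30 * 40, 12, 1)), 30, 40,
                 dimnames = list(sprintf("S%02d", 1:30), sprintf("G%02d", 1:40)))
  base[2, ] <- base[1, ] * 10
  v <- vsn_normalize(pkdprog:::new_proteome_matrix(base, is.na(base)))
  d <- v$matrix$values[2, ] - v$matrix$values[1, ]
  # a pure multiplicative shift becomes (at most) a constant offset
  expect_lt(sd(d), 1e-3)
  expect_true(all(v$fit$b > 0))
  # ranks preserved within each sample
  for (s in 1:5) {
    expect_identical(order(base[s, ]), order(v$matrix$values[s, ]))
  }
  # identical samples get identical calibration
  base2 <- base; base2[2, ] <- base2[1, ]
  v2 <- vsn_normalize(pkdprog:::new_proteome_matrix(base2, is.na(base2)))
  expect_equal(v2$fit$a[1], v2$fit$a[2], tolerance = 1e-2)
  expect_equal(v2$fit$b[1], v2$fit$b[2], tolerance = 1e-4)
  expect_error(vsn_normalize(random_matrix(1, 10)), ">= 2 samples")
})

test_that("vsn flattens the SD-vs-mean trend better than log2", {
  # additive + multiplicative noise: low-abundance proteins are dominated
  # by additive noise, which log2 inflates and the glog transform absorbs
  set.seed(5)
  n_s <- 40; n_p <- 150
  mu <- exp(runif(n_p, 3, 14))
  Y <- t(sapply(seq_len(n_s), function(s) {
    mu * exp(rnorm(n_p, 0, 0.15)) + rnorm(n_p, 0, 25)
  }))
  Y[Y <= 0] <- 0.1
  dimnames(Y) <- list(sprintf("S%02d", 1:n_s), sprintf("G%03d", 1:n_p))
  v <- vsn_normalize(pkdprog:::new_proteome_matrix(Y, is.na(Y)))
  rk <- rank(colMeans(Y))
  slope_vsn <- abs(coef(lm(apply(v$matrix$values, 2, sd) ~ rk))[2])
  slope_log <- abs(coef(lm(apply(log2(Y), 2, sd) ~ rk))[2])
  expect_lt(slope_vsn, slope_log)
})

test_that("low-tail imputation draws only from the bottom percentile", {
  m <- random_matrix(30, 40, seed = 3)
  miss <- matrix(FALSE, 30, 40)
  miss[sample(length(miss), 100)] <- TRUE
  m$values[miss] <- NA
  m$mask <- is.na(m$values)
  obs <- m$values[!is.na(m$values)]
  cutoff <- quantile(obs, 0.05, names = FALSE)

  imp <- impute_low(m, percentile = 5, seed = 11)
  expect_false(anyNA(imp$values))
  expect_true(all(imp$values[miss] <= cutoff))
  # mask still records the imputed cells
  expect_identical(imp$mask, m$mask)
  expect_identical(unname(imp$mask), miss)
  # deterministic under seed
  imp2 <- impute_low(m, percentile = 5, seed = 11)
  expect_identical(imp$values, imp2$values)
  # no missing -> unchanged
  m0 <- random_matrix(5, 10, seed = 4)
  expect_identical(impute_low(m0, seed = 1)$values, m0$values)
  # tiny pool -> informative error
  m3 <- random_matrix(4, 10, seed = 5)
  m3$values[1, 1] <- NA
  expect_error(impute_low(m3, percentile = 1, seed = 1), "percentile")
})

test_that("PCA outlier flagging finds a grossly shifted sample", {
  m <- random_matrix(30, 50, seed = 6)
  m$values[7, ] <- m$values[7, ] + 10   # +10 SD on all proteins
  flagged <- detect_outliers(m, k_mad = 5)
  expect_true("S007" %in% flagged)
  # homogeneous cohort: no flags
  expect_length(detect_outliers(random_matrix(40, 50, seed = 7), k_mad = 5), 0)
  expect_length(detect_outliers(m, k_mad = Inf), 0)
  expect_error(detect_outliers(random_matrix(2, 5)), ">= 3 samples")
})

test_that("batch correction removes location and scale batch effects", {
  set.seed(9)
  X <- matrix(rnorm(60 * 30, 10, 1), 60, 30,
              dimnames = list(sprintf("S%02d", 1:60), sprintf("G%02d", 1:30)))
  batch <- rep(1:2, each = 30)
  X[batch == 2, ] <- X[batch == 2, ] * sqrt(2) + 0.8   # offset + 2x variance
  m <- pkdprog:::new_proteome_matrix(X, is.na(X), batch = batch)
  out <- combat_correct(m)
  V <- out$matrix$values
  mean_diff <- abs(colMeans(V[batch == 1, ]) - colMeans(V[batch == 2, ]))
  # the 0.8 systematic offset is removed; what remains is sampling noise
  # of per-batch means (se ~ sqrt(2/30))
  expect_lt(max(mean_diff), 4 * sqrt(2 / 30))
  expect_lt(mean(mean_diff), 2 * sqrt(2 / 30))
  expect_lt(abs(mean(V[batch == 1, ]) - mean(V[batch == 2, ])), 0.05)
  v1 <- mean(apply(V[batch == 1, ], 2, var))
  v2 <- mean(apply(V[batch == 2, ], 2, var))
  expect_lt(abs(v1 / v2 - 1), 0.25)
  expect_true(all(out$fit$delta2 > 0))

  # single batch is a no-op
  m1 <- pkdprog:::new_proteome_matrix(X, is.na(X), batch = rep(1, 60))
  out1 <- combat_correct(m1)
  expect_equal(out1$matrix$values, X, tolerance = 1e-12)
  # singleton batch errors
  m2 <- pkdprog:::new_proteome_matrix(X, is.na(X), batch = c(3, batch[-1]))
  expect_error(combat_correct(m2), "singleton")
})

test_that("batch correction matches the reference implementation", {
  skip_if_not_installed("sva")
  set.seed(10)
  X <- matrix(rnorm(40 * 25, 10, 1), 40, 25,
              dimnames = list(sprintf("S%02d", 1:40), sprintf("G%02d", 1:25)))
  batch <- rep(1:2, each = 20)
  X[batch == 2, ] <- X[batch == 2, ] * 1.4 + 0.8
  m <- pkdprog:::new_proteome_matrix(X, is.na(X), batch = batch)
  ours <- combat_correct(m)$matrix$values
  ref <- suppressMessages(t(sva::ComBat(dat = t(X), batch = batch)))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("batch correction reduces batch-explained variance on PC1", {
  coh <- generate_cohort(cohort_config(n_patients = 80, seed = 12))
  pr <- generate_proteome(coh$ground_truth,
                          proteome_sim_config(n_proteins = 60, n_batches = 2,
                                              batch_shift_sd = 1.5, seed = 12))
  prep <- preprocess_report(as_raw_report(pr$report), batch = pr$batch,
                            seed = 12, remove_outliers = FALSE)
  before <- build_matrix(as_raw_report(pr$report), batch = pr$batch)
  before <- impute_low(vsn_normalize(filter_missing(before))$matrix, seed = 12)
  r2_batch <- function(m) {
    pc1 <- prcomp(m$values, center = TRUE, scale. = TRUE)$x[, 1]
    summary(lm(pc1 ~ factor(m$batch)))$r.squared
  }
  expect_lt(r2_batch(prep$matrix), r2_batch(before))
})

test_that("pipeline provenance is recorded in order and reruns bit-for-bit", {
  coh <- generate_cohort(cohort_config(n_patients = 40, seed = 13))
  pr <- generate_proteome(coh$ground_truth,
                          proteome_sim_config(n_proteins = 30, seed = 13))
  a <- preprocess_report(as_raw_report(pr$report), batch = pr$batch, seed = 13)
  b <- preprocess_report(as_raw_report(pr$report), batch = pr$batch, seed = 13)
  expect_identical(a$matrix$values, b$matrix$values)
  prov <- a$matrix$provenance
  expect_match(prov[1], "build_matrix")
  expect_match(prov[2], "filter_missing")
  expect_match(prov[3], "vsn_normalize")
  expect_match(prov[4], "impute_low")
  expect_match(prov[length(prov)], "combat_correct")
})
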