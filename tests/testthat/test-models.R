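test_that("model specs fix the protein panels", {
  expect_setequal(model_spec("proteome")$proteins,
                  c("SERPINF1", "GPX3", "AFM", "FERMT3", "CFHR1", "RARRES2"))
  expect_setequal(model_spec("proteome4")$proteins,
                  c("SERPINF1", "GPX3", "AFM", "CFHR1"))
  expect_length(model_spec("clinical")$proteins, 0)
  expect_true(model_spec("combined_genotype")$genotype)
})

test_that("design building codes terms as specified", {
  set.seed(1)
  n <- 40
  clin <- data.frame(patient_id = sprintf("P%02d", 1:n),
                     sex = rep(c("female", "male"), n / 2),
                     age = runif(n, 20, 70),
                     egfr = runif(n, 30, 100),
                     mayo_class = sample(c("1A", "1B", "1C", "1D", "1E"), n,
                                         replace = TRUE),
                     genotype = sample(c("PKD1_truncating",
                                         "PKD1_nontruncating", "PKD2"),
                                       n, replace = TRUE))
  X <- matrix(rnorm(n * 6, 15, 2), n,
              dimnames = list(clin$patient_id, model_spec("proteome")$proteins))
  d <- build_design(clin, X, model_spec("combined"))
  # z-scored proteins
  for (g in model_spec("proteome")$proteins) {
    expect_equal(mean(d$design[[g]]), 0, tolerance = 1e-10)
    expect_equal(sd(d$design[[g]]), 1, tolerance = 1e-10)
  }
  # 1D and 1E share a dummy; 1A/1B are the pooled reference
  expect_identical(d$design$mayo_1D1E,
                   as.numeric(clin$mayo_class %in% c("1D", "1E")))
  expect_true(all(d$design$mayo_1C[clin$mayo_class %in% c("1A", "1B")] == 0))
  expect_identical(d$design$sex_male, as.numeric(clin$sex == "male"))

  all_1a <- clin; all_1a$mayo_class <- "1A"
  d2 <- build_design(all_1a, X, model_spec("clinical"))
  expect_true(all(d2$design$mayo_1C == 0 & d2$design$mayo_1D1E == 0))

  expect_error(build_design(clin[, -3], X, model_spec("clinical")), "missing")
  badmayo <- clin; badmayo$mayo_class[1] <- "2A"
  expect_error(build_design(badmayo, X, model_spec("clinical")), "Mayo")
  # complete-case dropping is counted
  clin_na <- clin; clin_na$age[1:3] <- NA
  d3 <- build_design(clin_na, X, model_spec("clinical"))
  expect_equal(d3$n_dropped, 3)
})

test_that("OLS fit matches the closed-form normal-equation oracle", {
  x <- c(0.2, 1.1, 1.9, 3.2, 4.1, 5.0)
  y <- c(0.5, 2.0, 4.2, 6.0, 8.5, 9.9)
  fit <- fit_linear_model(data.frame(x = x), y)
  Xd <- cbind(1, x)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  res <- y - Xd %*% beta
  s2 <- sum(res^2) / (6 - 2)
  se <- sqrt(diag(s2 * solve(t(Xd) %*% Xd)))
  expect_equal(fit$terms$beta, as.numeric(beta), tolerance = 1e-10)
  p_oracle <- unname(2 * pt(-abs(as.numeric(beta) / se), df = 4))
  expect_equal(fit$terms$p, p_oracle, tolerance = 1e-10)
  expect_equal(fit$adj_r2, adjusted_r2(fit$r2, 6, 1), tolerance = 1e-12)

  # exact fit
  fit2 <- suppressWarnings(fit_linear_model(data.frame(x = x), 2 * x))
  expect_equal(fit2$terms$beta[2], 2, tolerance = 1e-10)
  expect_equal(fit2$r2, 1, tolerance = 1e-10)

  # rank deficiency names the collinear term
  expect_error(fit_linear_model(data.frame(x = x, x2 = 2 * x), y), "x2")
})

test_that("adjusted R2 reproduces the printed model statistics", {
  expect_equal(round(adjusted_r2(0.251, 212, 5), 3), 0.233)
  # printed 0.340 reflects rounding of the printed R2 itself
  expect_equal(adjusted_r2(0.375, 212, 11), 0.3406, tolerance = 1e-4)
  expect_lt(abs(adjusted_r2(0.375, 212, 11) - 0.340), 2e-3)
  expect_equal(adjusted_r2(1, 50, 6), 1)
  expect_error(adjusted_r2(0.5, 6, 5), "n > k")
})

test_that("published models load with the transcribed structure", {
  pm <- published_models()
  expect_setequal(names(pm), c("proteome", "clinical", "combined"))
  expect_equal(pm$proteome$n, 212)
  expect_equal(pm$proteome$r2, 0.334)
  expect_equal(pm$combined$adj_r2, 0.340)
  prot <- pm$proteome$terms
  expect_equal(prot$beta[prot$term == "GPX3"], 0.71)
  expect_equal(prot$ci_low[prot$term == "SERPINF1"], -0.96)
  expect_error(published_models("nope"), "unknown")
})

test_that("published-model evaluation is the stated linear predictor", {
  zeros <- as.list(setNames(rep(0, 6), model_spec("proteome")$proteins))
  expect_equal(evaluate_published("proteome", zeros), -2.74)
  up <- zeros; up$GPX3 <- 1
  expect_equal(evaluate_published("proteome", up) -
                 evaluate_published("proteome", zeros), 0.71)
  expect_error(evaluate_published("proteome", zeros[-1]), "SERPINF1")
  big <- zeros; big$AFM <- 1e6
  expect_error(evaluate_published("proteome", big), "plausibility")
})

test_that("fitted models round-trip through the published-model form", {
  set.seed(2)
  d <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- 1 + 2 * d$a - d$b + rnorm(30, 0, 0.1)
  fit <- fit_linear_model(d, y)
  pub <- as_published_model(fit)
  newd <- data.frame(a = rnorm(5), b = rnorm(5))
  expect_equal(evaluate_published(pub, newd),
               predict(fit, newd), tolerance = 1e-12)
})

test_that("Mayo classification boundaries and invariances", {
  expect_equal(mic_classify(150, 40)$mic_class, "1A")
  r500 <- mic_classify(500, 40)
  expect_equal(r500$growth_rate, log(500 / 150) / 40, tolerance = 1e-12)
  expect_equal(r500$mic_class, "1C")
  # r exactly 1.5%/yr falls in 1B (half-open intervals)
  httkv_15 <- 150 * exp(0.015 * 40)
  expect_equal(mic_classify(httkv_15, 40)$mic_class, "1B")
  # invariant to joint rescaling of volume and reference
  expect_equal(mic_classify(2 * 500, 40, reference_httkv = 300)$mic_class,
               r500$mic_class)
  expect_error(mic_classify(-5, 40), "positive")
  expect_error(mic_classify(500, 0), "positive")
})

test_that("MIC comparator predicts class-mean slopes", {
  set.seed(3)
  classes <- rep(c("1A", "1B", "1C", "1D"), each = 30)
  true_means <- c("1A" = -1, "1B" = -2, "1C" = -3, "1D" = -4.5)
  slopes <- true_means[classes] + rnorm(120, 0, 1)
  fit <- fit_mic_model(classes, slopes)
  pred <- predict_mic(fit, classes)
  # constant within class
  expect_true(all(tapply(pred, classes, function(v) diff(range(v))) == 0))
  # recovered class means within 95% CI half-width
  for (cl in names(true_means)) {
    expect_lt(abs(fit$class_means[cl] - true_means[cl]),
              2 * 1 / sqrt(30) * 2)
  }
  expect_error(fit_mic_model(rep("1A", 10), rnorm(10)), ">= 2")
})

test_that("repeated train/test cross-validation is seeded and consistent", {
  set.seed(4)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- -2 + d$x1 - 0.5 * d$x2 + rnorm(n, 0, 1)
  a <- cross_validate(d, y, reps = 30, seed = 7)
  b <- cross_validate(d, y, reps = 30, seed = 7)
  expect_identical(a$per_rep, b$per_rep)
  # noiseless response: perfect test R2
  y0 <- 1 + 2 * d$x1
  expect_equal(suppressWarnings(cross_validate(d, y0, reps = 10,
                                               seed = 1))$median_r2, 1,
               tolerance = 1e-10)
  # large-n: CV R2 close to full-data R2
  set.seed(5)
  n2 <- 2000
  d2 <- data.frame(x1 = rnorm(n2), x2 = rnorm(n2))
  y2 <- d2$x1 + rnorm(n2, 0, 1)
  cv <- cross_validate(d2, y2, reps = 50, seed = 2)
  full <- fit_linear_model(d2, y2)
  expect_lt(abs(cv$median_r2 - full$r2), 0.03)
})
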