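PROTEOME_PANEL <- c("SERPINF1", "GPX3", "AFM", "FERMT3", "CFHR1", "RARRES2")
PROTEOME4_PANEL <- setdiff(PROTEOME_PANEL, c("RARRES2", "FERMT3"))

#' Model term specification
#'
#' Named term sets for the eGFR-slope prediction models: the six-protein
#' proteome model, the clinical model (age, sex, eGFR, Mayo class), their
#' combination, genotype-extended variants, the four-protein model that
#' drops the two high-missingness markers (RARRES2, FERMT3), and the Mayo
#' Imaging Classification comparator.
#'
#' @param name One of `"proteome"`, `"clinical"`, `"combined"`,
#'   `"clinical_genotype"`, `"combined_genotype"`, `"proteome4"`, `"mic"`.
#' @return List of class `model_spec` with `name`, `proteins`, `clinical`
#'   (term names), `genotype`, `mic` (logical flags).
#' @export
model_spec <- function(name = c("proteome", "clinical", "combined",
                                "clinical_genotype", "combined_genotype",
                                "proteome4", "mic")) {
  name <- match.arg(name)
  proteins <- switch(name,
    proteome = PROTEOME_PANEL,
    combined = PROTEOME_PANEL,
    combined_genotype = PROTEOME_PANEL,
    proteome4 = PROTEOME4_PANEL,
    character(0))
  clinical <- if (name %in% c("clinical", "combined", "clinical_genotype",
                              "combined_genotype")) {
    c("age", "sex_male", "egfr", "mayo_1C", "mayo_1D1E")
  } else character(0)
  structure(list(name = name, proteins = proteins, clinical = clinical,
                 genotype = grepl("genotype", name), mic = name == "mic"),
            class = "model_spec")
}

mayo_dummies <- function(mayo_class) {
  known <- c("1A", "1B", "1C", "1D", "1E")
  bad <- setdiff(unique(as.character(mayo_class)), known)
  if (length(bad) > 0) {
    stop("unknown Mayo class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(mayo_1C = as.numeric(mayo_class == "1C"),
             mayo_1D1E = as.numeric(mayo_class %in% c("1D", "1E")))
}

#' Build a design matrix and response for a model specification
#'
#' Protein abundances are z-scored (scaling stored for later evaluation on
#' new data); Mayo class is coded as 1C and 1D-1E dummies against the
#' pooled 1A-1B reference; sex is coded male = 1; genotype as dummies for
#' PKD1-truncating and PKD1-non-truncating against PKD2. Rows with any
#' missing required term are dropped (complete-case), with counts
#' reported.
#'
#' @param clinical Data frame with `patient_id`, `sex`, `age` and, as the
#'   spec requires, `egfr` (eGFR at sampling), `mayo_class`, `genotype`.
#' @param matrix A `proteome_matrix` or plain matrix (samples x proteins),
#'   rows named by patient id; required when the spec includes proteins.
#' @param spec A [model_spec()].
#' @param slopes Optional named slope vector / data frame to attach as
#'   response.
#' @param scaling Optional previously stored protein scaling (data frame
#'   `gene`, `center`, `scale`) to apply instead of refitting.
#' @return List: `design` (data frame), `response` (numeric or NULL),
#'   `patient_id`, `scaling`, `n_dropped`.
#' @export
build_design <- function(clinical, matrix = NULL, spec = model_spec("combined"),
                         slopes = NULL, scaling = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  df <- data.frame(patient_id = clinical$patient_id, stringsAsFactors = FALSE)

  if (length(spec$clinical) > 0 || spec$mic) {
    need <- c("age", "sex", "egfr", "mayo_class")
    miss <- setdiff(need, names(clinical))
    if (length(miss) > 0 && !spec$mic) {
      stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  if (length(spec$clinical) > 0) {
    df$age <- clinical$age
    df$sex_male <- as.numeric(check_sex(clinical$sex) == "male")
    df$egfr <- clinical$egfr
    df <- cbind(df, mayo_dummies(clinical$mayo_class))
  }
  if (spec$genotype) {
    g <- as.character(clinical$genotype)
    df$pkd1_truncating <- as.numeric(g == "PKD1_truncating")
    df$pkd1_nontruncating <- as.numeric(g == "PKD1_nontruncating")
  }
  if (spec$mic) {
    df$mayo_class <- as.character(clinical$mayo_class)
  }

  if (length(spec$proteins) > 0) {
    X <- if (inherits(matrix, "proteome_matrix")) matrix$values else matrix
    if (is.null(X)) stop("proteome matrix required for spec '", spec$name, "'",
                         call. = FALSE)
    missing_p <- setdiff(spec$proteins, colnames(X))
    if (length(missing_p) > 0) {
      stop("matrix missing required protein(s): ",
           paste(missing_p, collapse = ", "), call. = FALSE)
    }
    idx <- match(df$patient_id, rownames(X))
    P <- X[idx, spec$proteins, drop = FALSE]
    if (is.null(scaling)) {
      ctr <- colMeans(P, na.rm = TRUE)
      scl <- apply(P, 2, stats::sd, na.rm = TRUE)
      scaling <- data.frame(gene = spec$proteins, center = ctr, scale = scl,
                            row.names = NULL, stringsAsFactors = FALSE)
    }
    for (g in spec$proteins) {
      sc <- scaling[scaling$gene == g, ]
      df[[g]] <- (P[, g] - sc$center) / sc$scale
    }
  }

  response <- NULL
  if (!is.null(slopes)) {
    if (is.data.frame(slopes)) {
      slopes <- stats::setNames(slopes$slope_annual, slopes$patient_id)
    }
    response <- unname(slopes[df$patient_id])
  }

  keep <- stats::complete.cases(df[, setdiff(names(df), "patient_id"),
                                   drop = FALSE])
  if (!is.null(response)) keep <- keep & !is.na(response)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (!is.null(response)) response <- response[keep]

  list(design = df, response = response, patient_id = df$patient_id,
       scaling = scaling, n_dropped = n_dropped)
}

#' Fit an ordinary least-squares progression model
#'
#' OLS of annual eGFR slope on the design terms, with per-term Wald
#' t-based 95% CIs, two-sided p-values, R^2 and adjusted R^2. Errors on
#' rank-deficient designs, naming the collinear terms.
#'
#' @param design Data frame of predictors (a `patient_id` column is
#'   ignored).
#' @param y Response vector (annual slopes).
#' @param scaling Optional protein scaling carried into the result for
#'   later prediction on raw data.
#' @return List of class `fitted_model`: `terms` (data frame `term`,
#'   `beta`, `ci_low`, `ci_high`, `p`), `n`, `r2`, `adj_r2`, `sigma`,
#'   `scaling`, `lm` (the underlying fit).
#' @export
fit_linear_model <- function(design, y, scaling = NULL) {
  X <- design[, setdiff(names(design), c("patient_id", "mayo_class")),
              drop = FALSE]
  stopifnot(nrow(X) == length(y))
  k <- ncol(X)
  if (nrow(X) <= k + 1) stop("need n > k + 1 observations", call. = FALSE)
  dat <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  terms <- data.frame(term = rownames(sm$coefficients),
                      beta = sm$coefficients[, 1],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      p = sm$coefficients[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, n = nrow(X), r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared, sigma = sm$sigma,
                 scaling = scaling, lm = fit),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model: n=%d, R2=%.3f, adj R2=%.3f\n",
              x$n, x$r2, x$adj_r2))
  print(transform(x$terms, beta = round(beta, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3), p = signif(p, 3)))
  invisible(x)
}

#' Predict from a fitted progression model
#'
#' @param object A `fitted_model`.
#' @param newdata Data frame of predictors on the same scale as the
#'   training design.
#' @param ... Unused.
#' @return Predicted annual slopes.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  unname(stats::predict(object$lm, newdata = newdata))
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - k - 1)` for `k` predictor terms.
#'
#' @param r2 Coefficient of determination.
#' @param n Number of observations.
#' @param k Number of predictor terms (excluding the intercept).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop("need n > k + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Load the transcribed published model coefficient sets
#'
#' Returns the published screening-cohort linear models (proteome,
#' clinical, combined) shipped with the package: per-term estimates, 95%
#' CIs and printed p-values, with n, R^2 and adjusted R^2. Protein terms
#' are on the z-scored abundance scale; clinical terms in natural units.
#'
#' @param name Optional single model name to return.
#' @return Named list of models (or one model), each of class
#'   `published_model` with elements `name`, `n`, `r2`, `adj_r2`, `terms`
#'   (data frame `term`, `beta`, `ci_low`, `ci_high`, `p_printed`).
#' @export
published_models <- function(name = NULL) {
  path <- system.file("extdata", "published_models.json", package = "pkdprog")
  raw <- jsonlite::read_json(path)
  raw[["_note"]] <- NULL
  models <- lapply(names(raw), function(nm) {
    m <- raw[[nm]]
    terms <- do.call(rbind, lapply(names(m$terms), function(tn) {
      t <- m$terms[[tn]]
      data.frame(term = tn, beta = t$beta, ci_low = t$ci[[1]],
                 ci_high = t$ci[[2]], p_printed = t$p,
                 stringsAsFactors = FALSE)
    }))
    structure(list(name = nm, n = m$n, r2 = m$r2, adj_r2 = m$adj_r2,
                   terms = terms),
              class = "published_model")
  })
  names(models) <- names(raw)
  if (!is.null(name)) {
    if (!name %in% names(models)) {
      stop("unknown published model: ", name, call. = FALSE)
    }
    return(models[[name]])
  }
  models
}

#' Evaluate a published model on new inputs
#'
#' Computes `intercept + sum(beta_j * x_j)` over the model's terms. Inputs
#' must be on the training scale: protein abundances z-scored, clinical
#' terms in natural units. A plausibility guard flags protein inputs whose
#' magnitude exceeds `z_bound` (likely unstandardized raw intensities).
#'
#' @param model A `published_model` (or name passed to
#'   [published_models()]).
#' @param inputs Named list/vector or data frame of term values; every
#'   non-intercept term must be supplied.
#' @param z_bound Plausibility bound for protein z-scores.
#' @return Predicted annual eGFR slope(s), mL/min/1.73 m^2 per year.
#' @export
evaluate_published <- function(model, inputs, z_bound = 10) {
  if (is.character(model)) model <- published_models(model)
  stopifnot(inherits(model, "published_model"))
  terms <- model$terms
  wanted <- setdiff(terms$term, "(Intercept)")
  if (is.data.frame(inputs)) inputs <- as.list(inputs)
  missing_t <- setdiff(wanted, names(inputs))
  if (length(missing_t) > 0) {
    stop("missing model term(s): ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  prot <- intersect(wanted, PROTEOME_PANEL)
  for (g in prot) {
    if (any(abs(inputs[[g]]) > z_bound, na.rm = TRUE)) {
      stop("protein input '", g, "' exceeds plausibility bound |z| <= ",
           z_bound, "; supply z-scored abundances", call. = FALSE)
    }
  }
  pred <- rep(terms$beta[terms$term == "(Intercept)"],
              length(inputs[[wanted[1]]]))
  for (tn in wanted) {
    pred <- pred + terms$beta[terms$term == tn] * inputs[[tn]]
  }
  pred
}

#' Convert a fitted model into a published-model coefficient set
#'
#' Serializes a `fitted_model` into the same structure as the transcribed
#' published models, so that [evaluate_published()] on the result
#' reproduces the fit's predictions exactly.
#'
#' @param fit A `fitted_model`.
#' @param name Model name to record.
#' @return A `published_model`.
#' @export
as_published_model <- function(fit, name = "custom") {
  stopifnot(inherits(fit, "fitted_model"))
  terms <- data.frame(term = fit$terms$term, beta = fit$terms$beta,
                      ci_low = fit$terms$ci_low, ci_high = fit$terms$ci_high,
                      p_printed = format(fit$terms$p, digits = 3),
                      stringsAsFactors = FALSE)
  structure(list(name = name, n = fit$n, r2 = fit$r2, adj_r2 = fit$adj_r2,
                 terms = terms),
            class = "published_model")
}

#' Mayo Imaging Classification from height-adjusted TKV
#'
#' The theoretical annual kidney growth rate is `r = ln(htTKV / 150) /
#' age`; classes are assigned on half-open intervals \[lo, hi): 1A below
#' 1.5%/yr, 1B \[1.5, 3)%, 1C \[3, 4.5)%, 1D \[4.5, 6)%, 1E at or above
#' 6%/yr.
#'
#' @param httkv_ml_per_m Height-adjusted total kidney volume (mL/m).
#' @param age Age in years.
#' @param reference_httkv Reference volume at birth (mL/m); the class is
#'   invariant to simultaneous rescaling of `httkv_ml_per_m` and this
#'   reference.
#' @return Data frame: `httkv_ml_per_m`, `age`, `growth_rate` (per year),
#'   `mic_class`.
#' @export
mic_classify <- function(httkv_ml_per_m, age, reference_httkv = 150) {
  if (any(httkv_ml_per_m <= 0)) stop("htTKV must be positive", call. = FALSE)
  if (any(age <= 0)) stop("age must be positive", call. = FALSE)
  r <- log(httkv_ml_per_m / reference_httkv) / age
  cls <- cut(r, breaks = c(-Inf, 0.015, 0.03, 0.045, 0.06, Inf),
             labels = c("1A", "1B", "1C", "1D", "1E"), right = FALSE)
  data.frame(httkv_ml_per_m = httkv_ml_per_m, age = age, growth_rate = r,
             mic_class = as.character(cls), stringsAsFactors = FALSE)
}

#' Fit the Mayo Imaging Classification comparator model
#'
#' Least-squares fit of annual slope on Mayo class indicators; the
#' prediction for a patient is the mean slope of their class, refit on the
#' cohort at hand.
#'
#' @param classes Character vector of Mayo classes (1A-1E).
#' @param slopes Annual slopes, same length.
#' @return A `fitted_model` whose design is the class factor; predictions
#'   via [predict_mic()].
#' @export
fit_mic_model <- function(classes, slopes) {
  classes <- as.character(classes)
  stopifnot(length(classes) == length(slopes))
  tab <- table(classes)
  if (length(tab) < 2) stop("need >= 2 Mayo classes present", call. = FALSE)
  if (any(tab < 2)) {
    stop("Mayo class(es) with < 2 patients: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  design <- data.frame(mic = factor(classes))
  fit <- stats::lm(slopes ~ mic, data = design)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  terms <- data.frame(term = rownames(sm$coefficients),
                      beta = sm$coefficients[, 1],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      p = sm$coefficients[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, n = length(slopes), r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared, sigma = sm$sigma,
                 scaling = NULL, lm = fit,
                 class_means = tapply(slopes, classes, mean)),
            class = c("mic_model", "fitted_model"))
}

#' Predict annual slope from a fitted MIC comparator
#'
#' @param model A `mic_model` from [fit_mic_model()].
#' @param classes Mayo classes of the patients to predict.
#' @return Predicted slopes (class mean slopes).
#' @export
predict_mic <- function(model, classes) {
  stopifnot(inherits(model, "mic_model"))
  unname(model$class_means[as.character(classes)])
}

#' Repeated train/test cross-validation of a progression model
#'
#' Draws `reps` seeded 2:1 train/test splits, refits the OLS model on each
#' training part (protein scaling refit within the split) and records test
#' R^2 and RMSE. Summaries are the median test R^2 and mean test RMSE.
#'
#' @param design Data frame of predictors.
#' @param y Response (annual slopes).
#' @param reps Number of splits.
#' @param train_fraction Training fraction (2:1 split = 2/3).
#' @param seed Integer seed.
#' @return List: `median_r2`, `mean_rmse`, `per_rep` (data frame `rep`,
#'   `r2_test`, `rmse_test`).
#' @export
cross_validate <- function(design, y, reps = 100, train_fraction = 2 / 3,
                           seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  X <- design[, setdiff(names(design), c("patient_id", "mayo_class")),
              drop = FALSE]
  n <- nrow(X)
  if (floor(n * train_fraction) <= ncol(X) + 1) {
    stop("not enough rows for the requested split", call. = FALSE)
  }
  set.seed(as.integer(seed))
  r2 <- rmse_v <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- sample(n, floor(n * train_fraction))
    fit <- fit_linear_model(X[tr, , drop = FALSE], y[tr])
    pred <- predict(fit, X[-tr, , drop = FALSE])
    obs <- y[-tr]
    ss_res <- sum((obs - pred)^2)
    ss_tot <- sum((obs - mean(obs))^2)
    r2[r] <- 1 - ss_res / ss_tot
    rmse_v[r] <- sqrt(mean((obs - pred)^2))
  }
  list(median_r2 = stats::median(r2), mean_rmse = mean(rmse_v),
       per_rep = data.frame(rep = seq_len(reps), r2_test = r2,
                            rmse_test = rmse_v))
}
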