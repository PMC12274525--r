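# Shared fixture builders (all programmatic, deterministic under seed).

# tiny long-format DIA report data frame
tiny_report <- function() {
  data.frame(
    Run = c("S1", "S1", "S2", "S2"),
    Protein.Group = c("PG1", "PG2", "PG1", "PG2"),
    Genes = c("GENEA", "GENEB", "GENEA", "GENEB"),
    Q.Value = c(0.001, 0.005, 0.02, 0.01),
    Intensity = c(100, 200, 110, 190),
    stringsAsFactors = FALSE)
}

# random samples x proteins matrix wrapped as proteome_matrix
random_matrix <- function(n_s = 20, n_p = 30, seed = 1, mean = 10, sd = 1,
                          raw_scale = FALSE) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n_s * n_p, mean, sd), n_s, n_p,
              dimnames = list(sprintf("S%03d", seq_len(n_s)),
                              sprintf("G%03d", seq_len(n_p))))
  if (raw_scale) X <- exp(X)
  pkdprog:::new_proteome_matrix(X, is.na(X))
}

# egfr series on a clean line: slope in units/year over n points
linear_series <- function(slope_annual = -3, baseline = 80, n = 5,
                          years = 4, patient_id = "P1",
                          start = as.Date("2015-01-01")) {
  days <- round(seq(0, years * 365.25, length.out = n))
  data.frame(patient_id = patient_id,
             date = start + days,
             egfr = baseline + slope_annual * days / 365.25,
             stringsAsFactors = FALSE)
}

# brute-force average-linkage clustering oracle: returns merge heights
average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}
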