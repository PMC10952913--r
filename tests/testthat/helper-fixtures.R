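# Shared fixtures and independent oracles used across the suite.

# Small simulation configuration for fast unit tests.
tiny_config <- function(n_genes = 60, conditions = c("US", "HL"), seed = 42,
                        ...) {
  sim_config(n_genes = n_genes, conditions = conditions, seed = seed, ...)
}

# Build an abundance_matrix directly from a values matrix and minimal sheet.
make_abundance <- function(values, sheet = NULL, unit = "CPM") {
  if (is.null(sheet)) {
    sheet <- data.frame(sample_id = colnames(values),
                        stringsAsFactors = FALSE)
  }
  structure(list(values = values, unit = unit, sample_sheet = sheet),
            class = "abundance_matrix")
}

# Brute-force Cliff's delta by explicit pair enumeration (the definition).
cliffs_delta_enum <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

# Exact two-sided permutation p-value for the rank-sum statistic.
ranksum_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  stats <- apply(idx, 2, function(i) sum(r[i]))
  centre <- n * (length(pooled) + 1) / 2
  mean(abs(stats - centre) >= abs(obs - centre) - 1e-9)
}

# Textbook OLS slope/intercept via the normal equations, independent of the
# package's fitting path.
ols_oracle <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(beta[2])
}

# Fractional-abundance object built by hand for decay_model tests.
make_fractional <- function(values, timepoint_min, condition = "US",
                            batch = 1L, replicate = NULL) {
  stopifnot(ncol(values) == length(timepoint_min))
  if (length(condition) == 1) condition <- rep(condition, ncol(values))
  if (length(batch) == 1) batch <- rep(batch, ncol(values))
  if (is.null(replicate)) replicate <- seq_len(ncol(values))
  sheet <- data.frame(sample_id = colnames(values), condition = condition,
                      timepoint_min = timepoint_min, batch = batch,
                      replicate = replicate, stringsAsFactors = FALSE)
  sheet$dT <- NA_real_
  for (cond in unique(condition)) {
    i <- sheet$condition == cond
    sheet$dT[i] <- sheet$timepoint_min[i] - min(sheet$timepoint_min[i])
  }
  structure(list(values = values, sample_sheet = sheet,
                 baseline = NULL, dropped = 0L),
            class = "fractional_abundance")
}
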