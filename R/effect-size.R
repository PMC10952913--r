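#' Cliff's delta
#'
#' Nonparametric effect size in \[-1, 1\]: the probability that a value
#' drawn from `x` exceeds one drawn from `y`, minus the reverse
#' probability. Ties contribute zero. Computed in O((n+m) log(n+m)) via
#' midranks, which is exactly equivalent to enumerating all pairs.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A single number in \[-1, 1\].
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("x and y must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))  # midranks handle ties as half-wins
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  2 * u / (n * m) - 1
}

#' Paired mean or median difference
#'
#' @param x,y Gene-aligned numeric vectors of equal length.
#' @param statistic `"mean_diff"` or `"median_diff"`.
#' @return `mean(x - y)` or `median(x - y)`.
#' @export
paired_difference <- function(x, y, statistic = c("mean_diff", "median_diff")) {
  statistic <- match.arg(statistic)
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  if (statistic == "mean_diff") mean(d) else stats::median(d)
}

#' Bootstrap a paired effect size
#'
#' Computes the point estimate on the original gene-aligned vectors and a
#' percentile confidence interval from bootstrap resamples of the gene
#' pairs (pairs are resampled jointly, preserving the pairing).
#'
#' @param x,y Gene-aligned numeric vectors (length >= 5).
#' @param statistic One of `"mean_diff"`, `"median_diff"`, `"cliffs_delta"`.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param conf_level Confidence level for the percentile interval.
#' @param seed Optional integer seed for reproducibility.
#' @return A one-row data frame of class `"effect_size_result"`:
#'   `statistic`, `estimate`, `ci_low`, `ci_high`, `n_boot`, `n_pairs`.
#' @export
bootstrap_effect <- function(x, y,
                             statistic = c("mean_diff", "median_diff",
                                           "cliffs_delta"),
                             n_boot = 10000, conf_level = 0.95, seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 5) stop("need at least 5 pairs")
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- switch(statistic,
    mean_diff = function(xi, yi) mean(xi - yi),
    median_diff = function(xi, yi) stats::median(xi - yi),
    cliffs_delta = cliffs_delta)
  est <- stat_fun(x, y)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    stat_fun(x[i], y[i])
  }, numeric(1))
  a <- (1 - conf_level) / 2
  ci <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
  structure(data.frame(statistic = statistic, estimate = est,
                       ci_low = ci[1], ci_high = ci[2],
                       n_boot = n_boot, n_pairs = n,
                       stringsAsFactors = FALSE),
            class = c("effect_size_result", "data.frame"))
}

#' Classify transcripts as destabilised, stabilised or unchanged
#'
#' Compares per-gene half-lives between two fitted conditions (restricted to
#' fits passing all filters in both). The classification threshold is the
#' absolute median half-life difference across the common genes: genes whose
#' difference is more negative than minus the threshold are destabilised,
#' more positive than the threshold stabilised, and otherwise unchanged
#' (boundary ties are unchanged, as "greater in magnitude" is read
#' strictly). The rule is antisymmetric in the two conditions.
#'
#' @param fits_a,fits_b [fit_all()] tables (e.g. HL and US), each covering a
#'   single condition.
#' @param contrast Optional label, e.g. `"HL_vs_US"`.
#' @return Data frame of class `"stability_calls"`: `gene_id`,
#'   `delta_halflife_min` (a minus b), `call`; the threshold (minutes) is in
#'   the `threshold` attribute.
#' @export
classify_stability <- function(fits_a, fits_b, contrast = NULL) {
  a <- fits_a[fits_a$passed_filters, c("gene_id", "halflife_min")]
  b <- fits_b[fits_b$passed_filters, c("gene_id", "halflife_min")]
  common <- intersect(a$gene_id, b$gene_id)
  if (length(common) == 0) stop("no common genes pass filters in both tables")
  d <- a$halflife_min[match(common, a$gene_id)] -
    b$halflife_min[match(common, b$gene_id)]
  thr <- abs(stats::median(d))
  call <- ifelse(d < -thr, "destabilised",
                 ifelse(d > thr, "stabilised", "unchanged"))
  out <- data.frame(gene_id = common, delta_halflife_min = d, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "contrast") <- contrast
  class(out) <- c("stability_calls", "data.frame")
  out
}

#' Compare fitted half-lives against external half-life datasets
#'
#' For each external dataset, half-life reductions (external minus internal)
#' are computed over the genes common to both, along with that dataset's
#' paired effect sizes. A gene is flagged against a dataset when its
#' half-life here is lower than the external value by at least the
#' dataset's median difference (and the reduction is positive); genes
#' flagged in at least `min_datasets` datasets form the
#' consistently-reduced-stability set.
#'
#' @param fits A [fit_all()] table for one condition; only fits passing all
#'   filters are used.
#' @param external Named list of data frames with columns `gene_id` and
#'   `halflife_min`.
#' @param min_datasets Minimum number of datasets a gene must be flagged in.
#' @return A list of class `"cross_study"`: `reduced_stability_genes`
#'   (character), `per_dataset` (data frame with `dataset`, `n_common`,
#'   `mean_diff`, `median_diff`, `cliffs_delta`, `n_flagged`) and `flags`
#'   (gene x dataset logical matrix).
#' @export
cross_study_compare <- function(fits, external, min_datasets = 3) {
  if (length(external) == 0) stop("need at least one external table")
  if (is.null(names(external))) {
    names(external) <- paste0("dataset", seq_along(external))
  }
  int <- fits[fits$passed_filters, c("gene_id", "halflife_min")]
  all_genes <- int$gene_id
  flags <- matrix(FALSE, length(all_genes), length(external),
                  dimnames = list(all_genes, names(external)))
  per <- list()
  for (nm in names(external)) {
    ext <- external[[nm]]
    common <- intersect(all_genes, ext$gene_id)
    if (length(common) == 0) {
      warning("no common genes with dataset ", nm, "; skipped")
      next
    }
    hi <- int$halflife_min[match(common, int$gene_id)]
    he <- ext$halflife_min[match(common, ext$gene_id)]
    diff <- he - hi  # positive = lower half-life here than externally
    med <- stats::median(diff)
    flagged <- diff >= med & diff > 0
    flags[common, nm] <- flagged
    per[[nm]] <- data.frame(dataset = nm, n_common = length(common),
                            mean_diff = mean(diff), median_diff = med,
                            cliffs_delta = cliffs_delta(he, hi),
                            n_flagged = sum(flagged),
                            stringsAsFactors = FALSE)
  }
  per_dataset <- do.call(rbind, per)
  rownames(per_dataset) <- NULL
  reduced <- all_genes[rowSums(flags) >= min_datasets]
  structure(list(reduced_stability_genes = reduced, per_dataset = per_dataset,
                 flags = flags),
            class = "cross_study")
}
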