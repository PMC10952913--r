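#' Select reference genes from mock-infiltrated samples
#'
#' Reference genes anchor decay-factor normalization: they should be highly
#' expressed and stable, so their apparent fold increase after transcription
#' inhibition measures the shrinkage of the total RNA pool rather than their
#' own regulation. Selection keeps genes whose mean log2(CPM + 0.01) across
#' mock samples is at or above the `abundance_pct` percentile AND whose
#' coefficient of variation of CPM is at or below the `cv_pct` percentile.
#' Boundary ties are retained, so degenerate inputs (all genes identical)
#' return every gene.
#'
#' @param abundance An `"abundance_matrix"` (CPM). If its sample sheet has a
#'   `treatment` column, only mock samples are used; otherwise all columns.
#' @param abundance_pct Abundance percentile cutoff (default 95).
#' @param cv_pct Coefficient-of-variation percentile cutoff (default 25).
#' @return Character vector of reference gene IDs.
#' @export
select_reference_genes <- function(abundance, abundance_pct = 95, cv_pct = 25) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  v <- abundance$values
  sh <- abundance$sample_sheet
  if (!is.null(sh) && "treatment" %in% colnames(sh) &&
      any(sh$treatment == "mock")) {
    v <- v[, sh$sample_id[sh$treatment == "mock"], drop = FALSE]
  }
  if (ncol(v) < 2) stop("need at least two mock samples to assess variance")
  mean_log <- rowMeans(log2(v + 0.01))
  mu <- rowMeans(v)
  cv <- apply(v, 1, stats::sd) / mu
  cv[!is.finite(cv)] <- NA
  abund_cut <- stats::quantile(mean_log, abundance_pct / 100, names = FALSE)
  cv_cut <- stats::quantile(cv, cv_pct / 100, na.rm = TRUE, names = FALSE)
  refs <- rownames(v)[mean_log >= abund_cut & !is.na(cv) & cv <= cv_cut]
  if (length(refs) == 0) {
    stop("no gene satisfies both percentile cutoffs; consider relaxing ",
         "abundance_pct/cv_pct")
  }
  refs
}

#' Compute per-(condition, timepoint) decay factors from reference genes
#'
#' The decay factor at (condition, timepoint) is the mean, over reference
#' genes, of the fold change of replicate-mean abundance in
#' cordycepin-treated samples relative to the first timepoint of that
#' condition. With stable references it estimates the apparent inflation of
#' relative abundances caused by the shrinking RNA pool; the factor at the
#' first timepoint is 1 by construction.
#'
#' @param abundance An `"abundance_matrix"` covering cordycepin samples (the
#'   sheet's `treatment` column is used to subset when present).
#' @param refs Character vector of reference gene IDs (all must be present).
#' @param geo_mean Use the geometric rather than arithmetic mean across
#'   reference genes.
#' @return A data frame of class `"decay_factors"`: `condition`,
#'   `timepoint_min`, `factor`.
#' @export
compute_decay_factors <- function(abundance, refs, geo_mean = FALSE) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  if (length(refs) == 0) stop("refs must be non-empty")
  missing_refs <- setdiff(refs, rownames(abundance$values))
  if (length(missing_refs) > 0) {
    stop("reference genes absent from matrix: ",
         paste(utils::head(missing_refs, 5), collapse = ", "))
  }
  v <- abundance$values
  sh <- abundance$sample_sheet
  if ("treatment" %in% colnames(sh) && any(sh$treatment == "cordycepin")) {
    keep <- sh$treatment == "cordycepin"
    v <- v[, sh$sample_id[keep], drop = FALSE]
    sh <- sh[keep, , drop = FALSE]
  }
  out <- list()
  for (cond in unique(sh$condition)) {
    sc <- sh[sh$condition == cond, , drop = FALSE]
    tps <- sort(unique(sc$timepoint_min))
    t_first <- tps[1]
    base <- rowMeans(v[refs, sc$sample_id[sc$timepoint_min == t_first],
                       drop = FALSE])
    if (any(base == 0)) stop("reference gene with zero baseline abundance")
    for (tp in tps) {
      m <- rowMeans(v[refs, sc$sample_id[sc$timepoint_min == tp],
                      drop = FALSE])
      fold <- m / base
      f <- if (geo_mean) exp(mean(log(fold))) else mean(fold)
      out[[length(out) + 1L]] <- data.frame(condition = cond,
                                            timepoint_min = tp, factor = f)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("decay_factors", "data.frame")
  res
}

#' Normalize cordycepin abundances to decay-factor-corrected fractions
#'
#' Each gene's abundance in a cordycepin sample is divided by its baseline
#' (replicate-mean abundance at the first timepoint of that condition) and
#' then by the decay factor of the sample's (condition, timepoint), yielding
#' fractional abundances whose log-linear slope against time is the decay
#' constant. Genes with a zero baseline in any covered condition are dropped
#' (their count is reported in the `dropped` attribute and a message).
#'
#' @param abundance An `"abundance_matrix"` containing the cordycepin
#'   samples (subset by the sheet's `treatment` column when present).
#' @param factors A [compute_decay_factors()] table covering every
#'   (condition, timepoint) present.
#' @return A list of class `"fractional_abundance"`: `values` (gene x
#'   cordycepin-sample matrix of decay-factor-corrected C/C_first ratios),
#'   `sample_sheet` (with a `dT` column, minutes since the condition's first
#'   timepoint) and `baseline` (gene x condition matrix).
#' @export
normalize_fractional <- function(abundance, factors) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  v <- abundance$values
  sh <- abundance$sample_sheet
  if ("treatment" %in% colnames(sh) && any(sh$treatment == "cordycepin")) {
    keep <- sh$treatment == "cordycepin"
    v <- v[, sh$sample_id[keep], drop = FALSE]
    sh <- sh[keep, , drop = FALSE]
  }
  conds <- unique(sh$condition)
  baseline <- matrix(NA_real_, nrow(v), length(conds),
                     dimnames = list(rownames(v), conds))
  sh$dT <- NA_real_
  norm <- v
  for (cond in conds) {
    sc <- sh$condition == cond
    t_first <- min(sh$timepoint_min[sc])
    sh$dT[sc] <- sh$timepoint_min[sc] - t_first
    baseline[, cond] <- rowMeans(v[, sh$sample_id[sc & sh$timepoint_min == t_first],
                                   drop = FALSE])
    for (tp in unique(sh$timepoint_min[sc])) {
      fr <- factors$factor[factors$condition == cond &
                             factors$timepoint_min == tp]
      if (length(fr) != 1) {
        stop("no decay factor for condition ", cond, " at t = ", tp)
      }
      cols <- sh$sample_id[sc & sh$timepoint_min == tp]
      norm[, cols] <- (v[, cols, drop = FALSE] / baseline[, cond]) / fr
    }
  }
  zero_base <- rowSums(baseline == 0) > 0
  if (any(zero_base)) {
    message(sum(zero_base), " gene(s) dropped for zero baseline abundance")
  }
  structure(list(values = norm[!zero_base, , drop = FALSE],
                 sample_sheet = sh,
                 baseline = baseline[!zero_base, , drop = FALSE],
                 dropped = sum(zero_base)),
            class = "fractional_abundance")
}

#' Exclude genes still induced after decay-factor normalization
#'
#' Genes whose replicate-mean normalized fractional abundance reaches
#' `threshold` or more at any post-baseline timepoint of any condition are
#' removed: residual apparent induction after normalization means the
#' exponential-decay model cannot apply.
#'
#' @param fractional A [normalize_fractional()] result.
#' @param threshold Fold-increase cutoff (default 1.5).
#' @return The `"fractional_abundance"` restricted to retained genes, with an
#'   `exclusion_report` attribute (`gene_id`, `max_mean_fraction`,
#'   `excluded`).
#' @export
exclude_induced <- function(fractional, threshold = 1.5) {
  stopifnot(inherits(fractional, "fractional_abundance"))
  v <- fractional$values
  sh <- fractional$sample_sheet
  post <- sh[sh$dT > 0, , drop = FALSE]
  max_mean <- rep(-Inf, nrow(v))
  for (cond in unique(post$condition)) {
    for (tp in unique(post$timepoint_min[post$condition == cond])) {
      cols <- post$sample_id[post$condition == cond & post$timepoint_min == tp]
      max_mean <- pmax(max_mean, rowMeans(v[, cols, drop = FALSE]))
    }
  }
  excluded <- max_mean >= threshold
  report <- data.frame(gene_id = rownames(v), max_mean_fraction = max_mean,
                       excluded = excluded, stringsAsFactors = FALSE)
  out <- fractional
  out$values <- v[!excluded, , drop = FALSE]
  out$baseline <- fractional$baseline[!excluded, , drop = FALSE]
  attr(out, "exclusion_report") <- report
  out
}
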