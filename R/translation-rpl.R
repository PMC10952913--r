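#' Relative polysome loading per gene and replicate
#'
#' RPL is the ratio of a gene's abundance (typically RPKM) in the
#' polysome-associated fraction to its abundance in total RNA, computed
#' replicate by replicate. Values near 1 indicate that a transcript is
#' polysome-associated in proportion to its total abundance; RPL is a proxy
#' for translational propensity, not a direct translation rate.
#'
#' @param total,polysome `"abundance_matrix"` objects whose sample sheets
#'   share pairing columns (any of `phase`, `condition`, `timepoint_min`,
#'   `replicate` present in both) identifying matched samples.
#' @return Long data frame of class `"rpl_table"`: `gene_id`, the pairing
#'   columns, and `rpl`. Replicates where the total abundance is zero are
#'   omitted for that gene.
#' @export
compute_rpl <- function(total, polysome) {
  stopifnot(inherits(total, "abundance_matrix"),
            inherits(polysome, "abundance_matrix"))
  genes <- intersect(rownames(total$values), rownames(polysome$values))
  if (length(genes) == 0) stop("no genes shared between the two matrices")
  keys <- intersect(c("phase", "condition", "timepoint_min", "replicate"),
                    intersect(colnames(total$sample_sheet),
                              colnames(polysome$sample_sheet)))
  if (length(keys) == 0) stop("sample sheets share no pairing columns")
  kt <- do.call(paste, c(total$sample_sheet[keys], sep = "|"))
  kp <- do.call(paste, c(polysome$sample_sheet[keys], sep = "|"))
  unpaired <- c(setdiff(kt, kp), setdiff(kp, kt))
  if (length(unpaired) > 0) {
    stop("unpairable samples (", paste(keys, collapse = "/"), "): ",
         paste(unique(unpaired), collapse = ", "))
  }
  out <- list()
  for (k in unique(kt)) {
    tot <- rowMeans(total$values[genes, total$sample_sheet$sample_id[kt == k],
                                 drop = FALSE])
    pol <- rowMeans(polysome$values[genes,
                                    polysome$sample_sheet$sample_id[kp == k],
                                    drop = FALSE])
    keep <- tot > 0
    meta <- total$sample_sheet[which(kt == k)[1], keys, drop = FALSE]
    out[[k]] <- data.frame(gene_id = genes[keep], meta,
                           rpl = pol[keep] / tot[keep],
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rpl_table", "data.frame")
  res
}

#' Format a percentage ratio as used for RPL-to-total comparisons
#'
#' @param pct_a,pct_b Percentages (e.g. fraction of transcripts with changed
#'   RPL and changed total mRNA).
#' @return The ratio `pct_a / pct_b` rounded to one decimal; the
#'   `"label"` attribute holds the conventional `"r:1"` string.
#' @export
change_ratio <- function(pct_a, pct_b) {
  if (pct_b <= 0) stop("denominator percentage must be positive")
  r <- round(pct_a / pct_b, 1)
  attr(r, "label") <- sprintf("%.1f:1", r)
  r
}

#' Classify genes on the fold-change grid of total mRNA versus RPL
#'
#' Genes are assigned to a 3 x 3 grid: up (fold change at or above
#' `threshold`), down (at or below `1/threshold`) or unchanged, separately
#' for total mRNA and RPL. The summary reports grid proportions, the
#' marginal fractions changed in either quantity and their ratio.
#'
#' @param fc_total,fc_rpl Named per-gene fold changes for one period; genes
#'   are aligned by name (the intersection is used).
#' @param threshold Fold-change cutoff (default 1.5).
#' @return A list of class `"quadrant_summary"`: `proportions` (3 x 3
#'   matrix, rows = total up/unchanged/down, columns = RPL), `n`,
#'   `pct_changed_rpl`, `pct_changed_total`, `ratio` (RPL:total, see
#'   [change_ratio()]).
#' @export
quadrant_classify <- function(fc_total, fc_rpl, threshold = 1.5) {
  genes <- intersect(names(fc_total), names(fc_rpl))
  if (length(genes) == 0) stop("no genes shared between fold-change vectors")
  cls <- function(fc) {
    factor(ifelse(fc >= threshold, "up",
                  ifelse(fc <= 1 / threshold, "down", "unchanged")),
           levels = c("up", "unchanged", "down"))
  }
  ct <- cls(fc_total[genes])
  cr <- cls(fc_rpl[genes])
  keep <- !is.na(ct) & !is.na(cr)
  tab <- table(total = ct[keep], rpl = cr[keep])
  props <- tab / sum(tab)
  pct_rpl <- 100 * sum(props[, c("up", "down")])
  pct_total <- 100 * sum(props[c("up", "down"), ])
  structure(list(proportions = props, n = sum(tab),
                 pct_changed_rpl = pct_rpl, pct_changed_total = pct_total,
                 ratio = if (pct_total > 0) change_ratio(pct_rpl, pct_total)
                         else NA_real_),
            class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf("Fold-change grid over %d genes\n", x$n))
  print(round(100 * unclass(x$proportions), 1))
  cat(sprintf("  changed RPL: %.1f%%, changed total: %.1f%% (%s)\n",
              x$pct_changed_rpl, x$pct_changed_total,
              attr(x$ratio, "label") %||% "NA"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign rapid-recovery-gene-downregulation (RRGD) categories
#'
#' RRGD genes are those upregulated at least `induction_threshold`-fold
#' after 30 min of high light. Category 3 genes decline again between 30
#' and 60 min of HL; category 2 genes decline only during recovery;
#' category 1 genes stay up throughout. "Declining" means a fold change at
#' or below `1/decline_threshold` between the relevant timepoints.
#'
#' @param expr Gene x timepoint matrix of (replicate-mean) total abundance
#'   with columns named `HL_0`, `HL_30`, `HL_60` and at least one `REC_*`
#'   column (e.g. `REC_30`); the last REC column is used for the recovery
#'   decline test.
#' @param induction_threshold Fold induction defining RRGD (default 3).
#' @param decline_threshold Fold decline separating the categories
#'   (default 1.5).
#' @param pseudo Pseudocount added to denominators to avoid division by
#'   zero.
#' @return Factor per gene with levels none/cat1/cat2/cat3.
#' @export
rrgd_classify <- function(expr, induction_threshold = 3,
                          decline_threshold = 1.5, pseudo = 0.01) {
  need <- c("HL_0", "HL_30", "HL_60")
  if (!all(need %in% colnames(expr))) {
    stop("expr must have columns ", paste(need, collapse = ", "))
  }
  rec_cols <- grep("^REC_", colnames(expr), value = TRUE)
  if (length(rec_cols) == 0) stop("expr must have at least one REC_* column")
  rec_last <- rec_cols[length(rec_cols)]
  induced <- expr[, "HL_30"] / (expr[, "HL_0"] + pseudo) >= induction_threshold
  late_decline <- expr[, "HL_60"] / (expr[, "HL_30"] + pseudo) <=
    1 / decline_threshold
  rec_decline <- expr[, rec_last] / (expr[, "HL_60"] + pseudo) <=
    1 / decline_threshold
  cat <- ifelse(!induced, "none",
                ifelse(late_decline, "cat3",
                       ifelse(rec_decline, "cat2", "cat1")))
  factor(cat, levels = c("none", "cat1", "cat2", "cat3"))
}

# Two-sided rank-sum test: exact enumeration below 8 observations per group
# (without ties), tie-corrected normal approximation otherwise.
ranksum_test <- function(x, y) {
  exact <- length(x) < 8 && length(y) < 8 && !any(duplicated(c(x, y)))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                                      alternative = "two.sided"))$p.value
}

#' Compare RPL fold-change distributions between RRGD categories
#'
#' For one time period, compares the per-gene RPL fold changes of every
#' pair of categories with a two-sided Wilcoxon rank-sum test and reports
#' group medians.
#'
#' @param rpl_fc Named per-gene RPL fold changes for one period.
#' @param categories Factor or character of RRGD categories, named by gene
#'   or aligned with `rpl_fc`.
#' @param min_n Minimum genes per group; smaller groups are skipped with
#'   `tested = FALSE`.
#' @return Data frame with one row per category pair: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `median_a`, `median_b`, `p_value`, `tested`.
#' @export
category_rpl_shift <- function(rpl_fc, categories, min_n = 2) {
  if (!is.null(names(categories)) && !is.null(names(rpl_fc))) {
    categories <- categories[names(rpl_fc)]
  }
  if (length(categories) != length(rpl_fc)) {
    stop("categories must align with rpl_fc")
  }
  categories <- as.character(categories)
  groups <- split(rpl_fc, categories)
  nm <- names(groups)
  out <- list()
  if (length(nm) < 2) stop("need at least two categories to compare")
  for (i in seq_len(length(nm) - 1)) {
    for (j in seq((i + 1), length(nm))) {
      a <- groups[[nm[i]]]; b <- groups[[nm[j]]]
      ok <- length(a) >= min_n && length(b) >= min_n
      out[[length(out) + 1L]] <- data.frame(
        group_a = nm[i], group_b = nm[j], n_a = length(a), n_b = length(b),
        median_a = stats::median(a), median_b = stats::median(b),
        p_value = if (ok) ranksum_test(a, b) else NA_real_,
        tested = ok, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percent attenuation of an induction response
#'
#' Quantifies how much a fold-change response is blunted by a treatment:
#' `100 * (1 - fc_treated / fc_control)`. For example, an induction of
#' 375-fold reduced to 4.5-fold is a 98.8% attenuation. The measure is
#' scale-invariant in the two fold changes.
#'
#' @param fc_control Fold change without the inhibitor (must be positive).
#' @param fc_treated Fold change with the inhibitor.
#' @param digits Decimal places to report (default 1; use 0 for
#'   whole-percent reporting).
#' @return Percent attenuation.
#' @export
attenuation_percent <- function(fc_control, fc_treated, digits = 1) {
  if (!is.finite(fc_control) || fc_control <= 0) {
    stop("fc_control must be positive")
  }
  round(100 * (1 - fc_treated / fc_control), digits)
}

#' Pearson correlation of log2 fold changes
#'
#' @param fc_a,fc_b Named per-gene fold changes; aligned by name, restricted
#'   to genes with finite positive values in both.
#' @return Pearson r of the log2 fold changes, or `NA` (with a warning) if
#'   either vector has zero variance or fewer than 3 genes remain.
#' @export
correlate_fold_changes <- function(fc_a, fc_b) {
  genes <- intersect(names(fc_a), names(fc_b))
  a <- fc_a[genes]; b <- fc_b[genes]
  keep <- is.finite(a) & is.finite(b) & a > 0 & b > 0
  if (sum(keep) < 3) {
    warning("fewer than 3 genes with finite fold changes in both")
    return(NA_real_)
  }
  la <- log2(a[keep]); lb <- log2(b[keep])
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) {
    warning("zero variance in log2 fold changes; correlation undefined")
    return(NA_real_)
  }
  stats::cor(la, lb)
}
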