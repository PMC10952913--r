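#' Construct and validate a decay time-course experiment
#'
#' The central input container of the pipeline: a gene x sample count matrix
#' plus a sample sheet describing condition (US/HL/REC), treatment
#' (mock/cordycepin), harvest timepoint, batch and replicate for every
#' column.
#'
#' @param counts Numeric gene x sample matrix with unique rownames (gene
#'   IDs). Non-negative; fractional estimated counts are accepted unless
#'   `strict_int = TRUE`.
#' @param sample_sheet Data frame with columns `sample_id`, `condition`,
#'   `treatment`, `timepoint_min`, `batch`, `replicate`; rows must match the
#'   count columns one-to-one.
#' @param gene_lengths Optional named vector of gene lengths in bp (required
#'   later for RPKM/TPM).
#' @param strict_int Require counts to be whole numbers.
#' @return A list of class `"tc_experiment"`.
#' @export
time_course_experiment <- function(counts, sample_sheet, gene_lengths = NULL,
                                   strict_int = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene IDs as rownames")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup) > 0) {
    stop("duplicated gene_id in counts: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  required <- c("sample_id", "condition", "treatment", "timepoint_min",
                "batch", "replicate")
  missing_cols <- setdiff(required, colnames(sample_sheet))
  if (length(missing_cols) > 0) {
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(colnames(counts))) colnames(counts) <- sample_sheet$sample_id
  only_counts <- setdiff(colnames(counts), sample_sheet$sample_id)
  only_sheet <- setdiff(sample_sheet$sample_id, colnames(counts))
  if (length(only_counts) > 0 || length(only_sheet) > 0) {
    stop("sample IDs do not match between counts and sheet.",
         if (length(only_counts)) paste0(" Counts only: ",
           paste(only_counts, collapse = ", "), "."),
         if (length(only_sheet)) paste0(" Sheet only: ",
           paste(only_sheet, collapse = ", "), "."))
  }
  sample_sheet <- sample_sheet[match(colnames(counts), sample_sheet$sample_id), ]
  rownames(sample_sheet) <- NULL
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (strict_int && any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers (strict_int = TRUE)")
  }
  bad_cond <- setdiff(unique(sample_sheet$condition), c("US", "HL", "REC"))
  if (length(bad_cond) > 0) {
    stop("unknown condition labels: ", paste(bad_cond, collapse = ", "))
  }
  bad_trt <- setdiff(unique(sample_sheet$treatment), c("mock", "cordycepin"))
  if (length(bad_trt) > 0) {
    stop("unknown treatment labels: ", paste(bad_trt, collapse = ", "))
  }
  if (any(sample_sheet$timepoint_min < 0)) {
    stop("timepoint_min must be non-negative")
  }
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(counts)]
    if (any(is.na(gene_lengths)) || any(gene_lengths <= 0)) {
      stop("gene_lengths must cover all genes with positive values")
    }
  }
  structure(list(counts = counts, sample_sheet = sample_sheet,
                 gene_lengths = gene_lengths),
            class = "tc_experiment")
}

#' @export
print.tc_experiment <- function(x, ...) {
  cat(sprintf("Time-course experiment: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$sample_sheet$condition, x$sample_sheet$treatment)
  print(tab)
  invisible(x)
}

#' Read a time-course experiment from TSV files
#'
#' Count matrices are tab-delimited with a header row of sample IDs and gene
#' IDs in the first column; gzip compression is handled transparently.
#'
#' @param counts_path Path to the gene x sample count TSV.
#' @param sheet_path Path to the sample-sheet TSV.
#' @param lengths_path Optional path to a two-column TSV (gene_id, length_bp).
#' @param strict_int Passed to [time_course_experiment()].
#' @return A validated [time_course_experiment()].
#' @export
read_experiment <- function(counts_path, sheet_path, lengths_path = NULL,
                            strict_int = FALSE) {
  for (p in c(counts_path, sheet_path, lengths_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- as.character(raw[[1]])
  sheet <- utils::read.delim(sheet_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.delim(lengths_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    lengths <- stats::setNames(as.numeric(lt[[2]]), as.character(lt[[1]]))
  }
  time_course_experiment(counts, sheet, gene_lengths = lengths,
                         strict_int = strict_int)
}

#' Convert counts to an abundance matrix (CPM, TPM or RPKM)
#'
#' CPM divides each count by its library size (column sum) times 1e6; RPKM
#' additionally divides by gene length in kb; TPM length-normalises first and
#' then rescales each column to sum to 1e6. Library-size scaling is used
#' throughout (no trimmed-mean normalization).
#'
#' @param exp A [time_course_experiment()].
#' @param unit One of `"CPM"`, `"TPM"`, `"RPKM"`.
#' @return A list of class `"abundance_matrix"` with elements `values`
#'   (gene x sample matrix), `unit` and `sample_sheet`.
#' @export
to_abundance <- function(exp, unit = c("CPM", "TPM", "RPKM")) {
  stopifnot(inherits(exp, "tc_experiment"))
  unit <- match.arg(unit)
  libs <- colSums(exp$counts)
  if (any(libs == 0)) {
    stop("zero column sum for sample(s): ",
         paste(colnames(exp$counts)[libs == 0], collapse = ", "))
  }
  if (unit %in% c("TPM", "RPKM") && is.null(exp$gene_lengths)) {
    stop(unit, " requires gene_lengths")
  }
  values <- switch(unit,
    CPM = sweep(exp$counts, 2, libs, "/") * 1e6,
    RPKM = sweep(exp$counts / (exp$gene_lengths / 1e3), 2, libs, "/") * 1e6,
    TPM = {
      rate <- exp$counts / exp$gene_lengths
      sweep(rate, 2, colSums(rate), "/") * 1e6
    })
  structure(list(values = values, unit = unit,
                 sample_sheet = exp$sample_sheet),
            class = "abundance_matrix")
}

#' Subset an abundance matrix by samples (and optionally genes)
#'
#' @param abundance An [to_abundance()] result.
#' @param samples Character sample IDs or a logical/integer index over
#'   columns.
#' @param genes Optional gene IDs to retain.
#' @return An `"abundance_matrix"` restricted to the selection. Unit-defining
#'   column sums are preserved from the full matrix (no re-normalization).
#' @export
subset_abundance <- function(abundance, samples = NULL, genes = NULL) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  v <- abundance$values
  sh <- abundance$sample_sheet
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, colnames(v)) else which(samples)
    if (anyNA(idx)) stop("unknown sample IDs in subset")
    v <- v[, idx, drop = FALSE]
    sh <- sh[idx, , drop = FALSE]
  }
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  structure(list(values = v, unit = abundance$unit, sample_sheet = sh),
            class = "abundance_matrix")
}

#' Detection filter on abundance
#'
#' Retains genes detected at or above `min_tpm` in strictly more than
#' `min_samples` of the given samples (by default the baseline-timepoint
#' samples, as abundance at the first harvest determines whether a decay
#' series is measurable at all).
#'
#' @param abundance An `"abundance_matrix"` (typically TPM).
#' @param min_tpm Detection threshold in abundance units.
#' @param min_samples Genes must exceed the threshold in strictly more than
#'   this many samples.
#' @param sample_subset Character vector of sample IDs to evaluate; defaults
#'   to samples at the earliest timepoint in the sheet.
#' @return Character vector of retained gene IDs.
#' @export
detection_filter <- function(abundance, min_tpm = 0.5, min_samples = 6,
                             sample_subset = NULL) {
  stopifnot(inherits(abundance, "abundance_matrix"))
  if (is.null(sample_subset)) {
    sh <- abundance$sample_sheet
    sample_subset <- sh$sample_id[sh$timepoint_min == min(sh$timepoint_min)]
  }
  if (length(sample_subset) == 0) stop("sample_subset is empty")
  idx <- match(sample_subset, colnames(abundance$values))
  if (anyNA(idx)) {
    stop("sample_subset contains unknown samples: ",
         paste(sample_subset[is.na(idx)], collapse = ", "))
  }
  hits <- rowSums(abundance$values[, idx, drop = FALSE] >= min_tpm)
  rownames(abundance$values)[hits > min_samples]
}
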