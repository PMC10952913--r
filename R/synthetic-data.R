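#' Generate ground-truth gene parameters for a synthetic decay experiment
#'
#' Draws per-gene, per-condition true half-lives, baseline abundances, decay
#' classes and RRGD categories. Reference genes are effectively stable
#' (half-life >= 1440 min) and drawn from a high-abundance, low-variance
#' stratum, mimicking the abundant housekeeping transcripts that
#' decay-factor normalization relies on. Under HL, a transcript-specific
#' subset of genes (`frac_destab`, RRGD genes first) has its half-life
#' multiplied by `hl_destab_shift`; recovery half-lives equal the unstressed
#' ones, so destabilisation is transient.
#'
#' @param config A [sim_config()].
#' @return A data frame of class `"truth_table"` with one row per
#'   (gene, condition): `gene_id`, `condition`, `true_halflife_min`,
#'   `baseline_abundance` (expected relative abundance at the baseline
#'   timepoint, arbitrary TPM-like units), `decay_class`
#'   (stable/slow/fast/rapid/reference), `rrgd_category` (none/cat1/cat2/cat3)
#'   and `hl_destabilised` (logical). Attributes: `rpl` (gene x polysome
#'   timepoint matrix of true relative polysome loading), `rpl_timepoints`
#'   (phase/minutes layout of the polysome course), `gene_lengths` (bp) and
#'   `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))

  n_ref <- round(config$frac_reference * n)
  n_rrgd <- round(config$frac_rrgd * n)
  is_ref <- rep(FALSE, n)
  if (n_ref > 0) is_ref[sample.int(n, n_ref)] <- TRUE
  rrgd <- rep("none", n)
  if (n_rrgd > 0) {
    pool <- which(!is_ref)
    picked <- sample(pool, min(n_rrgd, length(pool)))
    rrgd[picked] <- paste0("cat", sample(1:3, length(picked), replace = TRUE))
  }

  lr <- log(config$halflife_log_range)
  hl_us <- exp(stats::runif(n, lr[1], lr[2]))
  hl_us[is_ref] <- stats::runif(sum(is_ref), 1500, 6000)

  # transcript-specific destabilisation under HL: RRGD genes first, then a
  # random fill of other non-reference genes up to frac_destab
  n_destab <- round(config$frac_destab * sum(!is_ref))
  destab <- rep(FALSE, n)
  rrgd_idx <- which(rrgd != "none")
  destab[rrgd_idx[seq_len(min(length(rrgd_idx), n_destab))]] <- TRUE
  remaining <- n_destab - sum(destab)
  if (remaining > 0) {
    pool <- which(!is_ref & !destab)
    destab[sample(pool, min(remaining, length(pool)))] <- TRUE
  }

  # abundance strata: ordinary genes span several orders of magnitude,
  # reference genes sit near the top of the distribution with low spread
  base <- stats::rlnorm(n, meanlog = log(10), sdlog = 1.2)
  base[is_ref] <- stats::rlnorm(sum(is_ref), meanlog = log(400), sdlog = 0.3)

  decay_class <- ifelse(is_ref, "reference",
    ifelse(hl_us < 10, "rapid",
      ifelse(hl_us < 30, "fast",
        ifelse(hl_us < 100, "slow", "stable"))))

  per_cond <- function(cond) {
    hl <- hl_us
    b <- base
    if (cond == "HL") {
      hl[destab] <- hl_us[destab] * config$hl_destab_shift
      b[rrgd != "none"] <- b[rrgd != "none"] * config$rrgd_induction_fold
    } else if (cond == "REC") {
      # REC course starts while RRGD transcripts are still elevated
      b[rrgd != "none"] <- b[rrgd != "none"] * config$rrgd_induction_fold
    }
    data.frame(gene_id = gene_id, condition = cond,
               true_halflife_min = hl, baseline_abundance = b,
               decay_class = decay_class, rrgd_category = rrgd,
               hl_destabilised = destab, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, lapply(config$conditions, per_cond))
  rownames(truth) <- NULL

  # true relative polysome loading over the paired total/polysome course
  rpl_tp <- data.frame(phase = c("HL", "HL", "HL", "REC", "REC", "REC"),
                       minutes = c(0, 30, 60, 7.5, 15, 30))
  rpl <- matrix(1, n, nrow(rpl_tp),
                dimnames = list(gene_id, paste0(rpl_tp$phase, "_", rpl_tp$minutes)))
  # late-HL translational shift decoupled from total abundance
  n_shift <- round(config$frac_rpl_shift * n)
  shift_pool <- which(!is_ref & rrgd == "none")
  shift_idx <- sample(shift_pool, min(n_shift, length(shift_pool)))
  if (length(shift_idx) > 0) {
    up <- shift_idx[seq_len(ceiling(length(shift_idx) / 2))]
    dn <- setdiff(shift_idx, up)
    f <- config$rpl_shift_fold
    for (idx in list(list(i = up, f = f), list(i = dn, f = 1 / f))) {
      rpl[idx$i, "HL_60"] <- idx$f
      rpl[idx$i, "REC_7.5"] <- idx$f^0.75
      rpl[idx$i, "REC_15"] <- idx$f^0.5
      # back to 1 by 30 min REC
    }
  }
  # RRGD: categories 1 and 3 gain ribosome loading late in HL, all decline
  # during recovery
  for (cat in c("cat1", "cat3")) {
    i <- which(rrgd == cat)
    rpl[i, "HL_60"] <- 1.5
  }
  i <- which(rrgd != "none")
  rpl[i, "REC_7.5"] <- pmin(rpl[i, "REC_7.5"], 0.8)
  rpl[i, "REC_15"] <- pmin(rpl[i, "REC_15"], 0.7)
  rpl[i, "REC_30"] <- 0.7

  attr(truth, "rpl") <- rpl
  attr(truth, "rpl_timepoints") <- rpl_tp
  attr(truth, "gene_lengths") <- stats::setNames(
    round(stats::rlnorm(n, meanlog = log(1500), sdlog = 0.4)), gene_id)
  attr(truth, "config") <- config
  class(truth) <- c("truth_table", "data.frame")
  truth
}

# Expected absolute abundance (arbitrary units) for the cordycepin arm of one
# condition at a vector of timepoints; first-order exponential decay from the
# baseline timepoint, with optional lag during which decay is deferred.
expected_cord_abundance <- function(truth, config, condition, timepoints) {
  tr <- truth[truth$condition == condition, , drop = FALSE]
  t_first <- min(config$timepoints_min)
  kd <- log(2) / tr$true_halflife_min
  dt <- pmax(outer(rep(1, nrow(tr)), timepoints - t_first) - config$lag_min, 0)
  tr$baseline_abundance * exp(-kd * dt)
}

# Expected mock-arm abundance: flat except for RRGD transcripts, whose
# transcription-fed levels follow their category profile within the sampled
# window (category 3 declines during continued HL, categories 2 and 3
# decline during recovery).
expected_mock_abundance <- function(truth, config, condition, timepoints) {
  tr <- truth[truth$condition == condition, , drop = FALSE]
  t_first <- min(config$timepoints_min)
  dt <- pmax(0, timepoints - t_first)
  m <- matrix(1, nrow(tr), length(timepoints))
  half <- function(dt) 0.5^(dt / 30)  # halves over a 30-min window
  if (condition == "HL") {
    i <- tr$rrgd_category == "cat3"
    m[i, ] <- matrix(half(dt), sum(i), length(dt), byrow = TRUE)
  } else if (condition == "REC") {
    i <- tr$rrgd_category %in% c("cat2", "cat3")
    m[i, ] <- matrix(half(dt), sum(i), length(dt), byrow = TRUE)
  }
  tr$baseline_abundance * m
}

# Draw counts for one arm. `expected` is a gene x timepoint matrix of
# absolute expected abundances; relative abundances are renormalised to sum
# to one per sample BEFORE sampling, which is what creates the compositional
# artifact (stable genes apparently rise as the pool shrinks).
draw_arm_counts <- function(expected, timepoints, config, batch_factors,
                          sample_counts = TRUE) {
  n <- nrow(expected)
  cols <- list(); counts <- list()
  for (ti in seq_along(timepoints)) {
    for (r in seq_len(config$n_replicates)) {
      b <- ((r - 1L) %% config$n_batches) + 1L
      w <- expected[, ti] * batch_factors[, b]
      p <- w / sum(w)
      lib <- if (config$library_size_cv > 0) {
        cv2 <- config$library_size_cv^2
        stats::rlnorm(1, meanlog = log(config$library_size_mean) - log(1 + cv2) / 2,
                      sdlog = sqrt(log(1 + cv2)))
      } else config$library_size_mean
      mu <- lib * p
      y <- if (!sample_counts) {
        mu
      } else if (config$nb_dispersion > 0) {
        stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
      } else {
        stats::rpois(n, mu)
      }
      cols[[length(cols) + 1L]] <- data.frame(
        timepoint_min = timepoints[ti], replicate = r, batch = b,
        stringsAsFactors = FALSE)
      counts[[length(counts) + 1L]] <- y
    }
  }
  sheet <- do.call(rbind, cols)
  mat <- do.call(cbind, counts)
  rownames(mat) <- rownames(expected)
  list(counts = mat, sheet = sheet)
}

#' Simulate a mock/cordycepin decay time course with known truth
#'
#' For each requested condition the cordycepin arm decays exponentially from
#' the baseline timepoint at each gene's true rate, while the mock arm stays
#' at the (condition-specific) transcription-fed level. Per-sample relative
#' abundances are renormalised to sum to one before negative-binomial
#' sampling, reproducing the compositional artifact of transcription-shut-off
#' experiments; gene-by-batch log-normal factors and log-normal library sizes
#' complete the measurement model.
#'
#' @param truth A [generate_truth()] table.
#' @param config The [sim_config()] used to generate `truth`.
#' @param sample_counts If `FALSE`, return expected (real-valued) counts
#'   instead of sampling, i.e. the infinite-sequencing-depth limit. Useful
#'   for exactness tests.
#' @return A [time_course_experiment()] whose sample sheet has columns
#'   `sample_id`, `condition`, `treatment` (mock/cordycepin),
#'   `timepoint_min`, `batch`, `replicate`; the generating `truth` is kept in
#'   the `truth` attribute.
#' @export
simulate_decay_course <- function(truth, config, sample_counts = TRUE) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "sim_config"))
  missing_cond <- setdiff(config$conditions, unique(truth$condition))
  if (length(missing_cond) > 0) {
    stop("truth table lacks conditions: ", paste(missing_cond, collapse = ", "))
  }
  set.seed(derive_seed(config$seed, 2L))
  genes <- unique(truth$gene_id)
  bf <- matrix(exp(stats::rnorm(length(genes) * config$n_batches, 0,
                                config$batch_sd)),
               length(genes), config$n_batches, dimnames = list(genes, NULL))

  blocks <- list(); sheets <- list()
  for (cond in config$conditions) {
    for (trt in c("mock", "cordycepin")) {
      expected <- if (trt == "cordycepin") {
        expected_cord_abundance(truth, config, cond, config$timepoints_min)
      } else {
        expected_mock_abundance(truth, config, cond, config$timepoints_min)
      }
      rownames(expected) <- truth$gene_id[truth$condition == cond]
      expected <- expected[genes, , drop = FALSE]
      drawn <- draw_arm_counts(expected, config$timepoints_min, config, bf,
                             sample_counts = sample_counts)
      sh <- drawn$sheet
      sh$condition <- cond
      sh$treatment <- trt
      sh$sample_id <- sprintf("%s_%s_t%g_r%d", cond,
                              ifelse(trt == "mock", "M", "C"),
                              sh$timepoint_min, sh$replicate)
      colnames(drawn$counts) <- sh$sample_id
      blocks[[length(blocks) + 1L]] <- drawn$counts
      sheets[[length(sheets) + 1L]] <- sh
    }
  }
  counts <- do.call(cbind, blocks)
  sheet <- do.call(rbind, sheets)[, c("sample_id", "condition", "treatment",
                                      "timepoint_min", "batch", "replicate")]
  exp <- time_course_experiment(counts, sheet,
                                gene_lengths = attr(truth, "gene_lengths"),
                                strict_int = FALSE)
  attr(exp, "truth") <- truth
  exp
}

#' Simulate paired total and polysome-associated RNA-seq counts
#'
#' The total arm follows each gene's RRGD category profile over the light
#' stress/recovery course (default timepoints 0/30/60 min HL and 7.5/15/30
#' min REC); the polysome arm multiplies the total expectation by the gene's
#' true relative polysome loading at each timepoint before the same
#' renormalise-then-sample measurement model is applied.
#'
#' @inheritParams simulate_decay_course
#' @return A list of class `"polysome_course"` with elements `total` and
#'   `polysome`, each a list of `counts` (gene x sample matrix) and
#'   `sample_sheet` (`sample_id`, `phase`, `timepoint_min`, `batch`,
#'   `replicate`), plus `gene_lengths` and the `truth` attribute.
#' @export
simulate_polysome_course <- function(truth, config, sample_counts = TRUE) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "sim_config"))
  rpl <- attr(truth, "rpl")
  tp <- attr(truth, "rpl_timepoints")
  if (is.null(rpl) || is.null(tp)) {
    stop("truth table carries no true RPL trajectories")
  }
  set.seed(derive_seed(config$seed, 3L))
  tr <- truth[truth$condition == truth$condition[1], , drop = FALSE]
  genes <- tr$gene_id
  n <- length(genes)
  base <- tr$baseline_abundance

  # total-arm trajectory per RRGD category over the stress/recovery course
  profile_at <- function(cat, phase, minutes) {
    ind <- config$rrgd_induction_fold
    if (cat == "none") return(rep(1, length(minutes)))
    up <- pmin(1 + (ind - 1) * minutes / 30, ind)  # induction over first 30 min
    if (phase == "HL") {
      out <- up
      if (cat == "cat3") out[minutes > 30] <- ind * (1 / 3)^((minutes[minutes > 30] - 30) / 30)
      return(out)
    }
    # REC phase: cat1 stays up; cat2 declines back to 1 by 30 min REC;
    # cat3 enters REC already partly declined and keeps falling
    start <- if (cat == "cat3") ind / 3 else ind
    if (cat == "cat1") return(rep(ind, length(minutes)))
    pmax(1, start * (1 / start)^(minutes / 30))
  }
  expected_total <- matrix(0, n, nrow(tp), dimnames = list(genes, colnames(rpl)))
  for (j in seq_len(nrow(tp))) {
    for (cat in unique(tr$rrgd_category)) {
      i <- tr$rrgd_category == cat
      expected_total[i, j] <- base[i] * profile_at(cat, tp$phase[j], tp$minutes[j])
    }
  }
  expected_poly <- expected_total * rpl[genes, , drop = FALSE]

  bf <- matrix(exp(stats::rnorm(n * config$n_batches, 0, config$batch_sd)),
               n, config$n_batches, dimnames = list(genes, NULL))
  arm <- function(expected, tag) {
    drawn <- draw_arm_counts(expected, seq_len(nrow(tp)), config, bf,
                           sample_counts = sample_counts)
    sh <- drawn$sheet
    sh$phase <- tp$phase[sh$timepoint_min]
    sh$timepoint_min <- tp$minutes[sh$timepoint_min]
    sh$sample_id <- sprintf("%s_%s_t%g_r%d", tag, sh$phase, sh$timepoint_min,
                            sh$replicate)
    colnames(drawn$counts) <- sh$sample_id
    list(counts = drawn$counts,
         sample_sheet = sh[, c("sample_id", "phase", "timepoint_min",
                               "batch", "replicate")])
  }
  out <- list(total = arm(expected_total, "tot"),
              polysome = arm(expected_poly, "pol"),
              gene_lengths = attr(truth, "gene_lengths"))
  attr(out, "truth") <- truth
  class(out) <- "polysome_course"
  out
}

#' Write the components of a synthetic experiment as TSV files
#'
#' @param exp A [time_course_experiment()].
#' @param dir Output directory (created if absent).
#' @param gzip Compress the count matrix with gzip.
#' @return Invisibly, the paths written (`counts`, `sample_sheet`, and
#'   `truth` when the experiment carries one).
#' @export
write_experiment <- function(exp, dir, gzip = FALSE) {
  stopifnot(inherits(exp, "tc_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(dir, if (gzip) "counts.tsv.gz" else "counts.tsv")
  con <- if (gzip) gzfile(counts_path, "w") else file(counts_path, "w")
  utils::write.table(data.frame(gene_id = rownames(exp$counts), exp$counts,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  utils::write.table(exp$sample_sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- list(counts = counts_path, sample_sheet = sheet_path)
  truth <- attr(exp, "truth")
  if (!is.null(truth)) {
    paths$truth <- file.path(dir, "truth.tsv")
    utils::write.table(as.data.frame(truth), paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
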