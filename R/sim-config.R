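#' Simulation configuration for synthetic decay time courses
#'
#' Bundles and validates every tunable of the synthetic-data generator. The
#' defaults describe a scaled-down but structurally faithful cordycepin
#' time-course experiment: three post-infiltration harvests at 10-min
#' intervals per condition, four biological replicates split over two
#' experimental batches, negative-binomial counting noise, and half-lives
#' drawn log-uniformly between 5 and 200 min.
#'
#' @param n_genes Number of genes to simulate.
#' @param conditions Conditions to simulate; subset of `"US"` (unstressed),
#'   `"HL"` (high light) and `"REC"` (recovery).
#' @param timepoints_min Strictly increasing harvest times in minutes after
#'   infiltration. The first timepoint plays the role of the baseline (the
#'   earliest sample taken once transcriptional inhibition is effective).
#' @param n_replicates Biological replicates per (condition, treatment,
#'   timepoint).
#' @param n_batches Experimental batches; replicates are assigned to batches
#'   round-robin. Batches impose gene-wise multiplicative log-normal effects.
#' @param nb_dispersion Negative-binomial dispersion of the counting noise
#'   (`0` gives Poisson counts).
#' @param batch_sd Standard deviation, on the natural-log scale, of the
#'   gene-by-batch multiplicative effect.
#' @param library_size_mean,library_size_cv Mean and coefficient of variation
#'   of the log-normal library-size distribution.
#' @param halflife_log_range Two positive numbers: half-lives (minutes) of
#'   non-reference genes are drawn log-uniformly over this interval.
#' @param frac_reference Fraction of genes simulated as effectively stable
#'   (half-life >= 1440 min), highly abundant reference genes.
#' @param frac_rrgd Fraction of genes given rapid-recovery-gene-downregulation
#'   (RRGD) induction profiles.
#' @param frac_destab Fraction of non-reference genes whose half-life is
#'   shortened under HL (transcript-specific destabilisation). RRGD genes are
#'   preferentially included, mirroring the coupling between light induction
#'   and destabilisation.
#' @param hl_destab_shift Multiplicative half-life change under HL for the
#'   destabilised subset (values < 1 shorten the half-life).
#' @param rrgd_induction_fold Fold induction of RRGD genes after 30 min HL.
#' @param frac_rpl_shift Fraction of non-RRGD genes whose relative polysome
#'   loading shifts during late high light independently of total abundance.
#' @param rpl_shift_fold Magnitude of that late-HL RPL shift (half the genes
#'   go up by this fold, half down).
#' @param lag_min Per-gene lag (minutes) during which decay is deferred after
#'   inhibition, modelling residual transcriptional inertia. Default 0.
#' @param seed Integer seed; all randomness in the generator flows from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [generate_truth()], [simulate_decay_course()],
#'   [simulate_polysome_course()]
#' @export
sim_config <- function(n_genes = 2000,
                       conditions = c("US", "HL", "REC"),
                       timepoints_min = c(10, 20, 30),
                       n_replicates = 4,
                       n_batches = 2,
                       nb_dispersion = 0.05,
                       batch_sd = 0.1,
                       library_size_mean = 3e6,
                       library_size_cv = 0.2,
                       halflife_log_range = c(5, 200),
                       frac_reference = 0.05,
                       frac_rrgd = 0.05,
                       frac_destab = 0.5,
                       hl_destab_shift = 0.7,
                       rrgd_induction_fold = 8,
                       frac_rpl_shift = 0.2,
                       rpl_shift_fold = 2,
                       lag_min = 0,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), conditions = match.arg(conditions,
      c("US", "HL", "REC"), several.ok = TRUE),
    timepoints_min = as.numeric(timepoints_min),
    n_replicates = as.integer(n_replicates),
    n_batches = as.integer(n_batches),
    nb_dispersion = nb_dispersion, batch_sd = batch_sd,
    library_size_mean = library_size_mean, library_size_cv = library_size_cv,
    halflife_log_range = as.numeric(halflife_log_range),
    frac_reference = frac_reference, frac_rrgd = frac_rrgd,
    frac_destab = frac_destab, hl_destab_shift = hl_destab_shift,
    rrgd_induction_fold = rrgd_induction_fold,
    frac_rpl_shift = frac_rpl_shift, rpl_shift_fold = rpl_shift_fold,
    lag_min = lag_min, seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L) stop("n_genes must be a positive integer")
  if (length(cfg$timepoints_min) == 0L) {
    stop("timepoints_min must contain at least one timepoint")
  }
  if (any(diff(cfg$timepoints_min) <= 0)) {
    stop("timepoints_min must be strictly increasing")
  }
  if (any(cfg$timepoints_min < 0)) stop("timepoints_min must be non-negative")
  if (cfg$n_replicates < 1L || cfg$n_batches < 1L) {
    stop("n_replicates and n_batches must be positive")
  }
  if (cfg$nb_dispersion < 0 || cfg$batch_sd < 0 || cfg$library_size_cv < 0) {
    stop("dispersion, batch_sd and library_size_cv must be non-negative")
  }
  if (length(cfg$halflife_log_range) != 2L ||
      any(cfg$halflife_log_range <= 0) ||
      diff(cfg$halflife_log_range) <= 0) {
    stop("halflife_log_range must be an increasing pair of positive minutes")
  }
  fr <- c(cfg$frac_reference, cfg$frac_rrgd)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("frac_reference and frac_rrgd must lie in [0, 1] and sum to <= 1")
  }
  if (cfg$frac_destab < 0 || cfg$frac_destab > 1) {
    stop("frac_destab must lie in [0, 1]")
  }
  if (cfg$hl_destab_shift <= 0) stop("hl_destab_shift must be positive")
  if (cfg$lag_min < 0) stop("lag_min must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Decay time-course simulation configuration\n")
  cat(sprintf("  %d genes, conditions %s, timepoints %s min\n", x$n_genes,
              paste(x$conditions, collapse = "/"),
              paste(x$timepoints_min, collapse = "/")))
  cat(sprintf("  %d replicates in %d batches; NB dispersion %.3g, batch SD %.3g\n",
              x$n_replicates, x$n_batches, x$nb_dispersion, x$batch_sd))
  cat(sprintf("  half-lives log-uniform on [%g, %g] min; HL shift %.2f on %.0f%% of genes\n",
              x$halflife_log_range[1], x$halflife_log_range[2],
              x$hl_destab_shift, 100 * x$frac_destab))
  invisible(x)
}

# Derive a stream-specific seed from the master seed so that each generator
# stage is reproducible independently of the others. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483629L
}
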