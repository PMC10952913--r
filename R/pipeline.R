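#' Default pipeline configuration
#'
#' Collects every tunable of the half-life pipeline with its conventional
#' default: 95th/25th percentile reference-gene selection, 1.5-fold
#' post-normalization exclusion, alpha 0.05 with a 1440-min half-life cap,
#' 10,000 bootstrap resamples, 0.5-TPM detection in more than six baseline
#' samples, 3-fold RRGD induction and 1.5-fold fold-change grids.
#'
#' @param seed Integer seed driving the synthetic stage and the bootstrap.
#' @param sim A [sim_config()] describing the synthetic experiment to run
#'   (ignored when `counts`/`sheet` point at real data files).
#' @param counts,sheet Optional paths to a count TSV and sample sheet; when
#'   supplied, the simulate stage is skipped.
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param abundance_pct,cv_pct Reference-gene selection percentiles.
#' @param exclude_fold Post-normalization fold-increase exclusion threshold.
#' @param alpha,max_halflife Decay-fit vetting parameters.
#' @param n_boot Bootstrap resamples for condition contrasts.
#' @param min_tpm,min_samples Detection-filter parameters.
#' @param quadrant_fold,rrgd_fold Fold-change thresholds for the RPL grid
#'   and RRGD induction.
#' @return A list of class `"run_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            counts = NULL, sheet = NULL,
                            out_dir = tempfile("decaylab_run_"),
                            abundance_pct = 95, cv_pct = 25,
                            exclude_fold = 1.5, alpha = 0.05,
                            max_halflife = 1440, n_boot = 10000,
                            min_tpm = 0.5, min_samples = 6,
                            quadrant_fold = 1.5, rrgd_fold = 3) {
  structure(list(seed = as.integer(seed), sim = sim, counts = counts,
                 sheet = sheet, out_dir = out_dir,
                 abundance_pct = abundance_pct, cv_pct = cv_pct,
                 exclude_fold = exclude_fold, alpha = alpha,
                 max_halflife = max_halflife, n_boot = n_boot,
                 min_tpm = min_tpm, min_samples = min_samples,
                 quadrant_fold = quadrant_fold, rrgd_fold = rrgd_fold),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the half-life pipeline end to end
#'
#' Executes the stages simulate (unless real count/sheet paths are given),
#' abundance, normalize, halflife, and — when more than one condition is
#' present — the condition contrast. Stage outputs are written as TSVs to
#' `config$out_dir` together with a JSON manifest recording parameters,
#' seed, and gene counts after every filter, so a run can be reproduced
#' from the manifest alone.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results (`experiment`,
#'   `refs`, `factors`, `fractional`, `fits`, `contrast`) and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(package_version = as.character(utils::packageVersion("decaylab")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("sim", "counts", "sheet"))],
                   gene_counts = list())

  if (!is.null(config$counts)) {
    say("stage read: ", config$counts)
    exp <- read_experiment(config$counts, config$sheet)
  } else {
    say("stage simulate: ", config$sim$n_genes, " genes, seed ", config$seed)
    truth <- generate_truth(config$sim)
    exp <- simulate_decay_course(truth, config$sim)
    write_tsv(as.data.frame(truth), file.path(config$out_dir, "truth.tsv"))
    manifest$simulation <- config$sim[setdiff(names(config$sim), "conditions")]
  }
  manifest$gene_counts$input <- nrow(exp$counts)

  say("stage abundance")
  cpm <- to_abundance(exp, "CPM")
  detected <- if (!is.null(exp$gene_lengths)) {
    tpm <- to_abundance(exp, "TPM")
    detection_filter(tpm, min_tpm = config$min_tpm,
                     min_samples = min(config$min_samples,
                                       sum(tpm$sample_sheet$timepoint_min ==
                                             min(tpm$sample_sheet$timepoint_min)) - 1))
  } else rownames(cpm$values)
  cpm <- subset_abundance(cpm, genes = detected)
  manifest$gene_counts$detected <- length(detected)

  say("stage normalize")
  refs <- select_reference_genes(cpm, config$abundance_pct, config$cv_pct)
  factors <- compute_decay_factors(cpm, refs)
  fractional <- normalize_fractional(cpm, factors)
  fractional <- exclude_induced(fractional, config$exclude_fold)
  write_tsv(data.frame(gene_id = refs),
            file.path(config$out_dir, "reference_genes.tsv"))
  write_tsv(factors, file.path(config$out_dir, "decay_factors.tsv"))
  write_tsv(attr(fractional, "exclusion_report"),
            file.path(config$out_dir, "exclusion_report.tsv"))
  manifest$gene_counts$reference <- length(refs)
  manifest$gene_counts$retained_after_exclusion <- nrow(fractional$values)

  say("stage halflife")
  fits <- fit_all(fractional, alpha = config$alpha,
                  max_halflife = config$max_halflife)
  fits <- adjust_pvalues(fits)
  write_tsv(fits, file.path(config$out_dir, "decay_fits.tsv"))
  manifest$gene_counts$passed_filters <-
    as.list(tapply(fits$passed_filters, fits$condition, sum))

  contrast <- NULL
  conds <- unique(fits$condition)
  if (all(c("HL", "US") %in% conds)) {
    say("stage compare: HL vs US")
    hl <- fits[fits$condition == "HL" & fits$passed_filters, ]
    us <- fits[fits$condition == "US" & fits$passed_filters, ]
    common <- intersect(hl$gene_id, us$gene_id)
    x <- hl$halflife_min[match(common, hl$gene_id)]
    y <- us$halflife_min[match(common, us$gene_id)]
    contrast <- list(
      effect_sizes = rbind(
        bootstrap_effect(x, y, "mean_diff", n_boot = config$n_boot,
                         seed = derive_seed(config$seed, 11L)),
        bootstrap_effect(x, y, "median_diff", n_boot = config$n_boot,
                         seed = derive_seed(config$seed, 12L)),
        data.frame(statistic = "cliffs_delta", estimate = cliffs_delta(x, y),
                   ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L,
                   n_pairs = length(common))),
      calls = classify_stability(fits[fits$condition == "HL", ],
                                 fits[fits$condition == "US", ],
                                 contrast = "HL_vs_US"))
    write_tsv(contrast$effect_sizes,
              file.path(config$out_dir, "effect_sizes.tsv"))
    write_tsv(contrast$calls, file.path(config$out_dir, "stability_calls.tsv"))
    manifest$gene_counts$destabilised <-
      sum(contrast$calls$call == "destabilised")
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  say("done; outputs in ", config$out_dir)
  invisible(list(experiment = exp, refs = refs, factors = factors,
                 fractional = fractional, fits = fits, contrast = contrast,
                 manifest = manifest, out_dir = config$out_dir))
}

#' Run a small end-to-end demonstration on synthetic data
#'
#' Simulates a compact mock/cordycepin time course (500 genes, US and HL),
#' runs normalization, fitting and the condition contrast, and prints a
#' short summary.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (default: a temporary directory).
#' @return Invisibly, the [run_pipeline()] result.
#' @export
demo_pipeline <- function(seed = 7L, out_dir = tempfile("decaylab_demo_")) {
  cfg <- pipeline_config(
    seed = seed,
    sim = sim_config(n_genes = 500, conditions = c("US", "HL"), seed = seed),
    out_dir = out_dir, n_boot = 2000)
  res <- run_pipeline(cfg)
  fits <- res$fits
  for (cond in unique(fits$condition)) {
    ok <- fits$condition == cond & fits$passed_filters
    message(sprintf("%s: %d genes modelled, median half-life %.1f min",
                    cond, sum(ok), stats::median(fits$halflife_min[ok])))
  }
  if (!is.null(res$contrast)) {
    es <- res$contrast$effect_sizes
    md <- es[es$statistic == "median_diff", ]
    message(sprintf("HL - US paired median difference: %.2f min [%.2f, %.2f]",
                    md$estimate, md$ci_low, md$ci_high))
    message(sprintf("%d of %d common genes called destabilised under HL",
                    sum(res$contrast$calls$call == "destabilised"),
                    nrow(res$contrast$calls)))
  }
  invisible(res)
}
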