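test_that("config validation rejects malformed inputs", {
  expect_error(sim_config(timepoints_min = c(30, 20, 10)), "increasing")
  expect_error(sim_config(timepoints_min = numeric()), "at least one")
  expect_error(sim_config(frac_reference = 0.7, frac_rrgd = 0.5), "sum")
  expect_error(sim_config(halflife_log_range = c(200, 5)), "increasing pair")
})

test_that("truth generation is deterministic under a seed and covers all conditions", {
  cfg <- tiny_config(n_genes = 100, seed = 1)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  counts <- table(t1$gene_id)
  expect_true(all(counts == length(cfg$conditions)))
  expect_true(all(t1$true_halflife_min > 0))
  refs <- t1[t1$decay_class == "reference", ]
  expect_true(all(refs$true_halflife_min >= 1440))
})

test_that("hl_destab_shift scales HL half-lives of the destabilised subset", {
  t_id <- generate_truth(tiny_config(n_genes = 80, hl_destab_shift = 1.0))
  us <- t_id[t_id$condition == "US", ]
  hl <- t_id[t_id$condition == "HL", ]
  expect_equal(us$true_halflife_min, hl$true_halflife_min)

  cfg <- tiny_config(n_genes = 200, conditions = c("US", "HL", "REC"),
                     hl_destab_shift = 0.7, frac_destab = 1,
                     halflife_log_range = c(5, 200))
  tr <- generate_truth(cfg)
  us <- tr[tr$condition == "US", ]
  hl <- tr[tr$condition == "HL", ]
  nonref <- us$decay_class != "reference"
  d <- hl$true_halflife_min[nonref] - us$true_halflife_min[nonref]
  expect_lt(median(d), 0)
  expect_equal(hl$true_halflife_min[nonref], 0.7 * us$true_halflife_min[nonref])
  # REC equals US gene-wise
  rec <- tr[tr$condition == "REC", ]
  expect_equal(rec$true_halflife_min, us$true_halflife_min)
})

test_that("simulated counts are reproducible, non-negative integers with sane library sizes", {
  cfg <- tiny_config(n_genes = 50, conditions = "US", seed = 9)
  tr <- generate_truth(cfg)
  e1 <- simulate_decay_course(tr, cfg)
  e2 <- simulate_decay_course(tr, cfg)
  expect_identical(e1$counts, e2$counts)
  expect_true(all(e1$counts >= 0))
  expect_true(all(e1$counts == round(e1$counts)))
  libs <- colSums(e1$counts)
  # library sizes within a plausible band of the configured mean
  expect_true(all(libs > cfg$library_size_mean / 5))
  expect_true(all(libs < cfg$library_size_mean * 5))
})

test_that("expected cordycepin abundance halves per half-life before renormalisation", {
  cfg <- tiny_config(n_genes = 10, conditions = "US",
                     timepoints_min = c(10, 20, 30))
  tr <- generate_truth(cfg)
  tr$true_halflife_min[tr$condition == "US"][1] <- 10
  e <- decaylab:::expected_cord_abundance(tr, cfg, "US", c(10, 20, 30))
  expect_equal(e[1, 2] / e[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(e[1, 3] / e[1, 1], 0.25, tolerance = 1e-12)
})

test_that("log fractional abundance is exactly linear in the noise-free limit", {
  cfg <- tiny_config(n_genes = 30, conditions = "US", nb_dispersion = 0,
                     batch_sd = 0, library_size_cv = 0, n_batches = 1,
                     n_replicates = 1)
  tr <- generate_truth(cfg)
  exp_ <- simulate_decay_course(tr, cfg, sample_counts = FALSE)
  cpm <- to_abundance(exp_, "CPM")
  cord <- cpm$sample_sheet$treatment == "cordycepin"
  v <- cpm$values[, cpm$sample_sheet$sample_id[cord]]
  tp <- cpm$sample_sheet$timepoint_min[cord]
  # ratio of relative abundances between genes removes the compositional
  # renormalisation; its log slope must match the half-life difference
  kd_true <- log(2) / tr$true_halflife_min[tr$condition == "US"]
  lr <- log(v[1, ] / v[2, ])
  slope <- ols_oracle(lr, tp)
  expect_equal(slope, -(kd_true[1] - kd_true[2]), tolerance = 1e-9)
})

test_that("stable genes show the compositional artifact in raw counts", {
  # 10-gene toy: one near-immortal reference among fast decayers
  cfg <- sim_config(n_genes = 10, conditions = "US", n_replicates = 8,
                    n_batches = 1, batch_sd = 0, nb_dispersion = 0.01,
                    frac_reference = 0.1, frac_rrgd = 0,
                    halflife_log_range = c(8, 25), seed = 2)
  tr <- generate_truth(cfg)
  exp_ <- simulate_decay_course(tr, cfg)
  cpm <- to_abundance(exp_, "CPM")
  sh <- cpm$sample_sheet
  cord <- sh$treatment == "cordycepin"
  ref <- tr$gene_id[tr$decay_class == "reference"][1]
  first <- mean(cpm$values[ref, sh$sample_id[cord & sh$timepoint_min == 10]])
  last <- mean(cpm$values[ref, sh$sample_id[cord & sh$timepoint_min == 30]])
  expect_gt(last / first, 1)
})

test_that("polysome arm equals total arm when true RPL is one everywhere", {
  cfg <- tiny_config(n_genes = 40, conditions = "US", frac_rrgd = 0,
                     frac_rpl_shift = 0)
  tr <- generate_truth(cfg)
  expect_true(all(attr(tr, "rpl") == 1))
  pc <- simulate_polysome_course(tr, cfg, sample_counts = FALSE)
  rel_tot <- sweep(pc$total$counts, 2, colSums(pc$total$counts), "/")
  rel_pol <- sweep(pc$polysome$counts, 2, colSums(pc$polysome$counts), "/")
  expect_equal(rel_tot, rel_pol, tolerance = 1e-12, ignore_attr = TRUE)
  pc2 <- simulate_polysome_course(tr, cfg)
  pc3 <- simulate_polysome_course(tr, cfg)
  expect_identical(pc2$total$counts, pc3$total$counts)
  expect_identical(pc2$polysome$counts, pc3$polysome$counts)
})

test_that("an RPL doubling between 30 and 60 min HL is recovered from counts", {
  cfg <- sim_config(n_genes = 60, conditions = "US", n_replicates = 50,
                    nb_dispersion = 1e-4, batch_sd = 0, n_batches = 1,
                    frac_rrgd = 0, frac_rpl_shift = 0, seed = 8)
  tr <- generate_truth(cfg)
  rpl <- attr(tr, "rpl")
  rpl[1, ] <- c(1, 1, 2, 1, 1, 1)  # doubles at HL_60 only
  attr(tr, "rpl") <- rpl
  pc <- simulate_polysome_course(tr, cfg)
  lengths <- pc$gene_lengths
  mk <- function(arm) {
    v <- sweep(arm$counts / (lengths[rownames(arm$counts)] / 1e3), 2,
               colSums(arm$counts), "/") * 1e6
    make_abundance(v, arm$sample_sheet, unit = "RPKM")
  }
  tab <- compute_rpl(mk(pc$total), mk(pc$polysome))
  g1 <- tab[tab$gene_id == rownames(rpl)[1] & tab$phase == "HL", ]
  m30 <- mean(g1$rpl[g1$timepoint_min == 30])
  m60 <- mean(g1$rpl[g1$timepoint_min == 60])
  expect_equal(m60 / m30, 2, tolerance = 0.05)
})

test_that("written experiments round-trip through TSV", {
  cfg <- tiny_config(n_genes = 20, conditions = "US")
  tr <- generate_truth(cfg)
  exp_ <- simulate_decay_course(tr, cfg)
  dir <- withr::local_tempdir()
  paths <- write_experiment(exp_, dir)
  back <- read_experiment(paths$counts, paths$sample_sheet)
  expect_equal(back$counts, exp_$counts, ignore_attr = TRUE)
  expect_equal(back$sample_sheet$condition, exp_$sample_sheet$condition)
})
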