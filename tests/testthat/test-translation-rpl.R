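mk_paired <- function(tot, pol, timepoints = c(0, 30), reps = 1,
                      phase = "HL") {
  sheet <- expand.grid(replicate = seq_len(reps), timepoint_min = timepoints)
  sheet$phase <- phase
  mk <- function(v, tag) {
    colnames(v) <- sprintf("%s_t%g_r%d", tag, sheet$timepoint_min,
                           sheet$replicate)
    sh <- data.frame(sample_id = colnames(v), sheet,
                     stringsAsFactors = FALSE)
    make_abundance(v, sh, unit = "RPKM")
  }
  list(total = mk(tot, "tot"), polysome = mk(pol, "pol"))
}

test_that("RPL is the per-replicate polysome-to-total ratio", {
  tot <- matrix(c(10, 5), 2, 2, dimnames = list(c("a", "b"), NULL))
  pol <- matrix(c(20, 5), 2, 2, dimnames = list(c("a", "b"), NULL))
  p <- mk_paired(tot, pol)
  tab <- compute_rpl(p$total, p$polysome)
  expect_equal(tab$rpl[tab$gene_id == "a"], c(2, 2))
  expect_equal(tab$rpl[tab$gene_id == "b"], c(1, 1))
  # equal matrices give RPL identically one
  q <- mk_paired(tot, tot)
  expect_true(all(compute_rpl(q$total, q$polysome)$rpl == 1))
  # zero total omits that gene/replicate
  tot0 <- tot; tot0["b", 1] <- 0
  z <- mk_paired(tot0, pol)
  ztab <- compute_rpl(z$total, z$polysome)
  expect_equal(sum(ztab$gene_id == "b"), 1)
  # unpairable samples are named
  bad <- mk_paired(tot, pol)
  bad$polysome$sample_sheet$timepoint_min <- c(5, 5)
  expect_error(compute_rpl(bad$total, bad$polysome), "unpairable")
})

test_that("quadrant classification reproduces hand-built grids", {
  fc1 <- setNames(rep(1, 10), paste0("g", 1:10))
  q <- quadrant_classify(fc1, fc1)
  expect_equal(unname(q$proportions["unchanged", "unchanged"]), 1)
  expect_equal(q$pct_changed_rpl, 0)

  # 20 genes: 4 total-up, 2 total-down, 5 rpl-up, 3 rpl-down, overlaps chosen
  # by hand
  g <- paste0("g", 1:20)
  fct <- setNames(rep(1, 20), g); fcr <- setNames(rep(1, 20), g)
  fct[1:4] <- 2; fct[5:6] <- 0.5
  fcr[c(1, 2, 7, 8, 9)] <- 3; fcr[c(5, 10, 11)] <- 0.4
  q2 <- quadrant_classify(fct, fcr, threshold = 1.5)
  expect_equal(unname(q2$proportions["up", "up"]), 2 / 20)
  expect_equal(unname(q2$proportions["up", "unchanged"]), 2 / 20)
  expect_equal(unname(q2$proportions["down", "down"]), 1 / 20)
  expect_equal(q2$pct_changed_rpl, 100 * 8 / 20)
  expect_equal(q2$pct_changed_total, 100 * 6 / 20)
  # marginal consistency: changed-RPL fraction equals the six off-centre cells
  expect_equal(q2$pct_changed_rpl / 100,
               sum(q2$proportions[, c("up", "down")]))
  # boundary: fold change exactly at the threshold counts as changed
  qb <- quadrant_classify(setNames(1.5, "g1"), setNames(1 / 1.5, "g1"))
  expect_equal(unname(qb$proportions["up", "down"]), 1)
})

test_that("the published marginal percentages give their printed ratios", {
  expect_equal(as.numeric(change_ratio(25.9, 7.7)), 3.4)
  expect_identical(attr(change_ratio(25.9, 7.7), "label"), "3.4:1")
  expect_equal(as.numeric(change_ratio(20.8, 19.2)), 1.1)
  expect_equal(as.numeric(change_ratio(15.7, 16.8)), 0.9)
})

test_that("RRGD categories follow the induction and decline rules", {
  expr <- rbind(c(1, 5, 5, 5),    # stays up -> cat1
                c(1, 5, 5, 1),    # declines in REC -> cat2
                c(1, 5, 2, 1),    # declines 30->60 HL -> cat3
                c(1, 2, 2, 2),    # induced < 3-fold -> none
                c(1, 0.5, 0.5, 0.5))  # repressed -> none
  colnames(expr) <- c("HL_0", "HL_30", "HL_60", "REC_30")
  rownames(expr) <- paste0("g", 1:5)
  got <- rrgd_classify(expr, decline_threshold = 1.5)
  expect_equal(as.character(got), c("cat1", "cat2", "cat3", "none", "none"))
  # categories are mutually exclusive and exhaustive by construction
  expect_false(any(is.na(got)))
  expect_error(rrgd_classify(expr[, 1:3, drop = FALSE]), "REC")
})

test_that("category RPL comparisons behave under null and strong shifts", {
  set.seed(10)
  a <- rnorm(50, 1, 0.1)
  res_null <- category_rpl_shift(setNames(c(a, a), paste0("g", 1:100)),
                                 rep(c("cat1", "none"), each = 50))
  expect_gt(res_null$p_value, 0.5)
  expect_equal(res_null$median_a, res_null$median_b)
  res_shift <- category_rpl_shift(setNames(c(a, a + 10), paste0("g", 1:100)),
                                  rep(c("cat1", "none"), each = 50))
  expect_lt(res_shift$p_value, 0.001)
  small <- category_rpl_shift(setNames(rnorm(3), paste0("g", 1:3)),
                              c("cat1", "cat1", "none"), min_n = 2)
  expect_false(small$tested)
})

test_that("rank-sum p-values match exact permutation enumeration", {
  cases <- list(list(x = c(1.2, 3.4, 5.1, 7.9), y = c(2.2, 4.6, 6.3, 8.8)),
                list(x = c(10, 12, 15), y = c(11, 20, 25, 30)),
                list(x = c(0.1, 0.4, 0.9, 2.5, 4.2), y = c(1.1, 3.3, 5.5)),
                list(x = c(5, 6, 7, 8), y = c(1, 2, 3, 4)))
  for (cs in cases) {
    got <- decaylab:::ranksum_test(cs$x, cs$y)
    oracle <- ranksum_perm_p(cs$x, cs$y)
    expect_lt(abs(got - oracle) / oracle, 0.1)
  }
})

test_that("attenuation arithmetic reproduces the printed percentages", {
  expect_equal(attenuation_percent(375, 4.5), 98.8)
  expect_equal(attenuation_percent(32, 8, digits = 0), 75)
  expect_equal(attenuation_percent(32, 3.8, digits = 0), 88)
  expect_equal(attenuation_percent(32, 1.5, digits = 0), 95)
  expect_equal(attenuation_percent(7, 7), 0)
  # scale invariance
  expect_equal(attenuation_percent(375 * 3, 4.5 * 3), 98.8)
  expect_error(attenuation_percent(0, 1), "positive")
})

test_that("fold-change correlations behave at the identity and under independence", {
  set.seed(77)
  fc <- setNames(rlnorm(100), paste0("g", 1:100))
  expect_equal(correlate_fold_changes(fc, fc), 1)
  a <- setNames(rlnorm(1000), paste0("g", 1:1000))
  b <- setNames(rlnorm(1000), paste0("g", 1:1000))
  expect_lt(abs(correlate_fold_changes(a, b)), 0.1)
  expect_warning(r0 <- correlate_fold_changes(setNames(rep(2, 5), paste0("g", 1:5)),
                                              fc[1:5]), "zero variance")
  expect_true(is.na(r0))
})

test_that("a staged RPL course decouples and recouples fold-change correlations", {
  cfg <- sim_config(n_genes = 300, seed = 19, n_replicates = 3,
                    nb_dispersion = 0.01, frac_rpl_shift = 0.3)
  tr <- generate_truth(cfg)
  pc <- simulate_polysome_course(tr, cfg)
  lengths <- pc$gene_lengths
  mk <- function(arm) {
    v <- sweep(arm$counts / (lengths[rownames(arm$counts)] / 1e3), 2,
               colSums(arm$counts), "/") * 1e6
    make_abundance(v, arm$sample_sheet, unit = "RPKM")
  }
  tot <- mk(pc$total); pol <- mk(pc$polysome)
  mab <- function(ab, ph, t) {
    sh <- ab$sample_sheet
    rowMeans(ab$values[, sh$sample_id[sh$phase == ph & sh$timepoint_min == t],
                       drop = FALSE])
  }
  fc <- function(a, b) (a + 0.01) / (b + 0.01)
  early <- correlate_fold_changes(fc(mab(tot, "HL", 30), mab(tot, "HL", 0)),
                                  fc(mab(pol, "HL", 30), mab(pol, "HL", 0)))
  late <- correlate_fold_changes(fc(mab(tot, "HL", 60), mab(tot, "HL", 30)),
                                 fc(mab(pol, "HL", 60), mab(pol, "HL", 30)))
  rec <- correlate_fold_changes(fc(mab(tot, "REC", 30), mab(tot, "REC", 15)),
                                fc(mab(pol, "REC", 30), mab(pol, "REC", 15)))
  expect_gt(early, late)   # decoupling during late stress
  expect_gt(rec, late)     # recovery restores the coupling
})
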