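#' @importFrom lme4 lmer lmerControl isSingular fixef VarCorr refit
NULL

# Ordinary least-squares log-linear decay fit via the normal equations.
# y = ln(fractional abundance), dt = minutes since the first timepoint.
ols_decay <- function(y, dt) {
  n <- length(y)
  sxx <- sum((dt - mean(dt))^2)
  slope <- sum((dt - mean(dt)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(dt)
  res <- y - intercept - slope * dt
  rss <- max(sum(res^2), 0)
  tss <- sum((y - mean(y))^2)
  df <- n - 2L
  if (df < 1L) {  # saturated two-point fit: slope defined, no inference
    return(list(slope = slope, se = NA_real_, p = NA_real_, r2 = 1,
                f = NA_real_, n = n, method = "ols"))
  }
  se <- sqrt(rss / df / sxx)
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  p <- 2 * stats::pt(-abs(tval), df)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  list(slope = slope, se = se, p = p, r2 = r2, f = tval^2, n = n,
       method = "ols")
}

# Mixed-effects decay fit (random intercept per batch) with Wald t-test on
# the time coefficient against residual degrees of freedom, and conditional
# R^2 by variance partition (fixed + random over total).
mixed_decay <- function(y, dt, batch, template = NULL) {
  dat <- data.frame(y = y, dT = dt, batch = factor(batch))
  m <- tryCatch({
    if (!is.null(template)) {
      suppressWarnings(suppressMessages(lme4::refit(template, newresp = y)))
    } else {
      suppressWarnings(suppressMessages(
        lme4::lmer(y ~ dT + (1 | batch), data = dat, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))))
    }
  }, error = function(e) NULL)
  if (is.null(m) || lme4::isSingular(m, tol = 1e-4)) return(NULL)
  co <- summary(m)$coefficients
  slope <- co["dT", "Estimate"]
  se <- co["dT", "Std. Error"]
  n <- length(y)
  df <- n - 2L
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  p <- 2 * stats::pt(-abs(tval), df)
  vf <- stats::var(as.numeric(stats::model.matrix(m) %*% lme4::fixef(m)))
  vr <- sum(sapply(lme4::VarCorr(m), function(v) v[1, 1]))
  ve <- stats::sigma(m)^2
  r2c <- (vf + vr) / (vf + vr + ve)
  list(slope = slope, se = se, p = p, r2 = r2c, f = tval^2, n = n,
       method = "mixed")
}

fit_decay_core <- function(value, time_min, batch = NULL, min_obs = 2L,
                           max_zero_frac = 0.5) {
  t0 <- min(time_min)
  usable <- is.finite(value) & value > 0
  if (mean(!usable) > max_zero_frac) {
    return(list(reason = "sparse", n = sum(usable)))
  }
  y <- log(value[usable])
  dt <- time_min[usable] - t0
  b <- if (!is.null(batch)) batch[usable] else NULL
  if (length(y) < min_obs || length(unique(dt)) < 2) {
    return(list(reason = "too_few_points", n = length(y)))
  }
  fit <- NULL
  if (!is.null(b) && length(unique(b)) >= 2) fit <- mixed_decay(y, dt, b)
  if (is.null(fit)) fit <- ols_decay(y, dt)
  fit$reason <- NA_character_
  fit
}

#' Fit exponential decay to a single gene's fractional-abundance series
#'
#' Fits `ln(value) ~ time` by a linear mixed-effects model with a random
#' intercept per batch when two or more batches are present, falling back to
#' ordinary least squares when the random-effect variance is singular or
#' only one batch exists. The decay constant is minus the slope and the
#' half-life is `ln(2)/kd`. Zero observations are dropped from the log
#' response; series with more than half zeros are skipped (`fail_reason =
#' "sparse"`). The p-value is a Wald t-test on the time coefficient with
#' residual degrees of freedom; `conditional_r2` is the fixed-plus-random
#' variance fraction (equal to the ordinary R^2 for OLS fits).
#'
#' @param value Positive fractional abundances (zeros allowed, dropped).
#' @param time_min Harvest times in minutes (origin at the minimum).
#' @param batch Optional batch labels for the random intercept.
#' @param alpha Significance level used for `passed_filters`.
#' @param max_halflife Half-life cap in minutes for `passed_filters`
#'   (default 1440, one day).
#' @return One-row data frame with `kd`, `halflife_min`, `slope_se`,
#'   `conditional_r2`, `f_stat`, `p_value`, `n_obs`, `fit_method`,
#'   `passed_filters`, `fail_reason`.
#' @export
fit_decay <- function(value, time_min, batch = NULL, alpha = 0.05,
                      max_halflife = 1440) {
  stopifnot(length(value) == length(time_min))
  fit <- fit_decay_core(value, time_min, batch)
  as_fit_row(fit, alpha = alpha, max_halflife = max_halflife)
}

as_fit_row <- function(fit, gene_id = NA_character_, condition = NA_character_,
                       alpha = 0.05, max_halflife = 1440) {
  if (!is.null(fit$reason) && !is.na(fit$reason)) {
    return(data.frame(gene_id = gene_id, condition = condition, kd = NA_real_,
                      halflife_min = NA_real_, slope_se = NA_real_,
                      conditional_r2 = NA_real_, f_stat = NA_real_,
                      p_value = NA_real_, n_obs = fit$n,
                      fit_method = NA_character_, passed_filters = FALSE,
                      fail_reason = fit$reason, stringsAsFactors = FALSE))
  }
  kd <- -fit$slope
  hl <- if (is.finite(kd) && kd > 0) log(2) / kd else NA_real_
  passed <- is.finite(fit$p) && fit$p < alpha && is.finite(kd) && kd > 0 &&
    !is.na(hl) && hl <= max_halflife
  reason <- if (passed) NA_character_ else if (!is.finite(fit$p) ||
    fit$p >= alpha) "not_significant" else if (kd <= 0) "negative_kd" else
    "halflife_above_cap"
  data.frame(gene_id = gene_id, condition = condition, kd = kd,
             halflife_min = hl, slope_se = fit$se,
             conditional_r2 = fit$r2, f_stat = fit$f, p_value = fit$p,
             n_obs = fit$n, fit_method = fit$method, passed_filters = passed,
             fail_reason = reason, stringsAsFactors = FALSE)
}

#' Fit decay models for every gene and condition
#'
#' Runs [fit_decay()] over all genes of a normalized fractional-abundance
#' object, condition by condition. Baseline samples enter as ordinary
#' observations at `dT = 0` (their mean log response is zero by
#' construction of the normalization) unless `include_baseline = FALSE`.
#' Genes sharing the template design (no dropped zeros) reuse a single
#' mixed-model fit via response refitting for speed; fits with singular
#' random-effect variance fall back to OLS and record `fit_method = "ols"`.
#'
#' @param fractional A [normalize_fractional()] (optionally
#'   [exclude_induced()]) result.
#' @param alpha Significance level for the time-coefficient test.
#' @param max_halflife Half-life cap in minutes; fits above it fail the
#'   filter, matching the removal of effectively non-decaying genes.
#' @param include_baseline Include the first-timepoint samples as dT = 0
#'   observations.
#' @param conditions Conditions to fit (default: all in the sheet).
#' @return Data frame of class `"decay_fits"`, one row per
#'   (gene, condition), with a `summary` attribute counting fit outcomes.
#' @export
fit_all <- function(fractional, alpha = 0.05, max_halflife = 1440,
                    include_baseline = TRUE, conditions = NULL) {
  stopifnot(inherits(fractional, "fractional_abundance"))
  sh <- fractional$sample_sheet
  v <- fractional$values
  if (is.null(conditions)) conditions <- unique(sh$condition)
  rows <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    sel <- sh$condition == cond
    if (!include_baseline) sel <- sel & sh$dT > 0
    cols <- sh$sample_id[sel]
    dt <- sh$dT[sel]
    batch <- sh$batch[sel]
    vv <- v[, cols, drop = FALSE]
    use_mixed <- length(unique(batch)) >= 2

    template <- NULL
    if (use_mixed) {
      complete <- which(rowSums(!(vv > 0) | !is.finite(vv)) == 0)
      if (length(complete) > 0) {
        dat <- data.frame(y = log(vv[complete[1], ]), dT = dt,
                          batch = factor(batch))
        template <- tryCatch(suppressWarnings(suppressMessages(
          lme4::lmer(y ~ dT + (1 | batch), data = dat, REML = TRUE,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore")))),
          error = function(e) NULL)
      }
    }
    fit_one <- function(g) {
      value <- vv[g, ]
      usable <- is.finite(value) & value > 0
      if (use_mixed && all(usable) && !is.null(template)) {
        fit <- mixed_decay(log(value), dt, batch, template = template)
        if (is.null(fit)) fit <- ols_decay(log(value), dt)
        fit$reason <- NA_character_
        return(as_fit_row(fit, rownames(vv)[g], cond, alpha, max_halflife))
      }
      as_fit_row(fit_decay_core(value, sh$timepoint_min[sel], batch,
                                min_obs = 3L),
                 rownames(vv)[g], cond, alpha, max_halflife)
    }
    rows[[ci]] <- do.call(rbind, lapply(seq_len(nrow(vv)), fit_one))
  }
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  smry <- as.data.frame(table(condition = fits$condition,
                              outcome = ifelse(fits$passed_filters, "passed",
                                ifelse(is.na(fits$fail_reason), "other",
                                       fits$fail_reason))))
  attr(fits, "summary") <- smry[smry$Freq > 0, ]
  class(fits) <- c("decay_fits", "data.frame")
  fits
}

#' Adjust decay-fit p-values for multiple testing
#'
#' @param fits A [fit_all()] table.
#' @param method Adjustment method passed to [stats::p.adjust()]
#'   (default Benjamini-Hochberg).
#' @return `fits` with a `p_adj` column.
#' @export
adjust_pvalues <- function(fits, method = "BH") {
  fits$p_adj <- stats::p.adjust(fits$p_value, method = method)
  fits
}

#' Sensitivity of half-life estimates to timepoint omission
#'
#' Refits the decay models after dropping the listed harvest timepoints and
#' compares half-lives over genes modelled (passing all filters) in both
#' designs, reporting the gene counts and the Pearson correlation. Omitting
#' early timepoints typically reduces the number of modellable genes while
#' leaving the half-lives of the surviving genes essentially unchanged.
#'
#' @param fractional A [normalize_fractional()] result.
#' @param omit Numeric timepoints (minutes) to drop.
#' @inheritParams fit_all
#' @return A list of class `"sensitivity_report"`: `omitted_timepoints`,
#'   `n_modelled_full`, `n_modelled_omitted`, `n_common`, `pearson_r`,
#'   `r_squared`, plus both fit tables.
#' @export
timepoint_sensitivity <- function(fractional, omit = numeric(),
                                  alpha = 0.05, max_halflife = 1440,
                                  conditions = NULL) {
  stopifnot(inherits(fractional, "fractional_abundance"))
  sh <- fractional$sample_sheet
  keep <- !(sh$timepoint_min %in% omit)
  for (cond in unique(sh$condition)) {
    left <- unique(sh$timepoint_min[keep & sh$condition == cond])
    if (length(left) < 2) {
      stop("omission leaves fewer than two timepoints for condition ", cond)
    }
  }
  full <- fit_all(fractional, alpha = alpha, max_halflife = max_halflife,
                  conditions = conditions)
  sub <- fractional
  sub$values <- fractional$values[, sh$sample_id[keep], drop = FALSE]
  sub$sample_sheet <- sh[keep, , drop = FALSE]
  # re-origin dT within each condition so the first remaining timepoint is 0
  for (cond in unique(sub$sample_sheet$condition)) {
    i <- sub$sample_sheet$condition == cond
    sub$sample_sheet$dT[i] <-
      sub$sample_sheet$timepoint_min[i] - min(sub$sample_sheet$timepoint_min[i])
  }
  omitted <- fit_all(sub, alpha = alpha, max_halflife = max_halflife,
                     conditions = conditions)
  key <- function(f) paste(f$gene_id, f$condition)
  fm <- full[full$passed_filters, ]
  om <- omitted[omitted$passed_filters, ]
  common <- intersect(key(fm), key(om))
  r <- if (length(common) >= 3) {
    stats::cor(fm$halflife_min[match(common, key(fm))],
               om$halflife_min[match(common, key(om))])
  } else NA_real_
  structure(list(omitted_timepoints = omit,
                 n_modelled_full = nrow(fm),
                 n_modelled_omitted = nrow(om),
                 n_common = length(common),
                 pearson_r = r, r_squared = r^2,
                 fits_full = full, fits_omitted = omitted),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Timepoint-omission sensitivity (omitted: %s)\n",
              if (length(x$omitted_timepoints)) paste(x$omitted_timepoints,
                collapse = ", ") else "none"))
  cat(sprintf("  modelled genes: %d (full) vs %d (omitted); %d in common\n",
              x$n_modelled_full, x$n_modelled_omitted, x$n_common))
  cat(sprintf("  Pearson r = %.3f (R^2 = %.3f) over common genes\n",
              x$pearson_r, x$r_squared))
  invisible(x)
}
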