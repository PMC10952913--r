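---
title: "Estimating mRNA half-lives from transcription-inhibition time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mRNA half-lives from transcription-inhibition time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

When transcription is halted chemically (cordycepin, actinomycin D), the
abundance of each mRNA decays at its intrinsic first-order rate,

$$C_g(t) = C_g(t_0)\, e^{-k_{d,g}\,(t - t_0)}, \qquad
  t_{1/2,g} = \frac{\ln 2}{k_{d,g}},$$

so a log-linear regression of abundance against time estimates the decay
constant $k_d$ gene by gene. RNA-seq, however, measures *relative*
abundance: as unstable transcripts are degraded without replacement, the
total pool shrinks, and stable transcripts occupy a growing share of every
library. In counts-per-million units a perfectly stable transcript appears
*induced* — the compositional artifact. Left uncorrected, this biases every
decay constant downward and flips the sign for the most stable genes.

`decaylab` implements the full correction-and-estimation chain for
stress/recovery designs with unstressed (US), high-light (HL) and recovery
(REC) conditions, each sampled at a few closely spaced timepoints after
infiltration of the inhibitor, with a mock-infiltrated arm as control.

## Decay-factor normalization

Reference genes are selected from mock-treated samples as those that are
both highly expressed (mean $\log_2(\mathrm{CPM}+0.01)$ at or above the
95th percentile) and stable across samples (coefficient of variation of CPM
at or below the 25th percentile). Such transcripts are assumed not to decay
appreciably over the sampled window, so their mean fold change in
cordycepin-treated samples at each (condition, timepoint) — the *decay
factor* — estimates the apparent inflation of the relative-abundance scale.
Every gene's fraction $C/C_{first}$ (relative to its replicate-mean
abundance at the first harvested timepoint of that condition) is divided by
this factor. Two consequences are exact by construction and are verified in
the test suite:

* the factor at the first timepoint is 1;
* the mean normalized trajectory of the reference set is 1 at every
  (condition, timepoint).

Genes still showing a replicate-mean normalized fraction of at least 1.5 at
any later timepoint are excluded — apparent induction after correction
means first-order decay cannot describe them. Percentile boundaries are
computed with linear-interpolation quantiles and boundary ties are
retained, so a degenerate matrix in which all genes are identical selects
every gene rather than none. The "mean fold increase" across references is
an arithmetic mean by default; a geometric mean is available
(`geo_mean = TRUE`) because the choice is not determined by the procedure's
description and the difference is second-order for factors near 1.

## The gene-wise decay model

For each gene and condition the response is
$\ln(\text{normalized fraction})$ and the predictor is minutes since the
first timepoint. When two or more experimental batches are present, a
linear mixed-effects model with a random intercept per batch is fitted with
`lme4`; if the random-effect variance is singular (common with two
batches), the fit falls back to ordinary least squares and records
`fit_method = "ols"`. The p-value is a Wald t-test of the time coefficient
with $n-2$ residual degrees of freedom — a deliberate simplification of
Satterthwaite-type corrections that is conservative to negligible at these
sample sizes (verified against OLS in the zero-batch-variance limit, where
the two paths agree in $k_d$ to better than 1%). The conditional $R^2$
follows the variance-partition definition,
$(\sigma^2_f + \sigma^2_r)/(\sigma^2_f + \sigma^2_r + \sigma^2_e)$.

Numerical choices:

* Zero normalized values are dropped from the log response rather than
  floored — flooring biases $k_d$ upward for low-abundance genes. Series
  with more than 50% zeros are skipped (`fail_reason = "sparse"`), and the
  pipeline requires at least three usable observations spanning two
  timepoints. The single-series API additionally supports the saturated
  two-point fit, whose slope equals the analytic solution
  $t\,\ln 2 / \ln(C_{first}/C_{last})$ but carries no inference.
* Baseline samples enter as ordinary observations at $dT = 0$; the
  normalization makes their mean response zero, so no information is
  double-counted.
* Fits are vetted with $p < 0.05$ (unadjusted, matching the genome-wide
  screening convention; Benjamini–Hochberg adjustment is applied by
  `adjust_pvalues()` for small-panel use), $k_d > 0$, and
  $t_{1/2} \le 1440$ min — a transcript that takes more than a day to halve
  is indistinguishable from stable over a 20–30 min window.

Because the regression design is identical for every gene without dropped
zeros, the mixed model is fitted once per condition and re-used by response
refitting, which makes the genome-wide loop roughly an order of magnitude
faster than gene-by-gene `lmer` calls without changing any estimate.

## Condition contrasts and cross-study comparisons

Half-life differences between conditions are summarised with estimation
statistics rather than hypothesis tests: the paired mean difference, paired
median difference and Cliff's delta, with percentile confidence intervals
from 10,000 bootstrap resamples of gene pairs (pairs are resampled jointly;
the point estimate is computed on the original data). Cliff's delta is
computed from midranks in $O(n\log n)$, which is algebraically identical to
all-pairs enumeration with ties counting zero; the test suite checks this
equivalence exhaustively on small vectors.

A transcript is called *destabilised* in a contrast when its half-life
reduction exceeds, in magnitude, the absolute median difference across the
genes common to both fits (strictly — boundary ties are "unchanged"). The
rule is antisymmetric under swapping the conditions. Note that when every
transcript shifts by a common proportional factor this median rule labels
about half of them destabilised by construction; transcript-*specific*
destabilisation is what it detects.

For cross-study comparisons each external half-life table is compared on
common genes; a gene is flagged against a dataset when its half-life here
is lower by at least that dataset's median difference (with a positive
reduction). A strictly-greater reading would un-flag every gene when all
reductions are identical, which contradicts the intended behaviour on
constructed uniform shifts, so the boundary is inclusive. Genes flagged in
at least `min_datasets` datasets form the consistently-less-stable set.

## Translation analysis

Relative polysome loading (RPL) is the replicate-wise ratio of
polysome-associated to total abundance (RPKM), a proxy for translational
propensity. Period-wise fold changes of total mRNA and RPL are placed on a
3×3 grid at a 1.5-fold threshold; the marginal fractions changed in either
quantity and their one-decimal "r:1" ratio summarise how much translational
change is decoupled from abundance change. RRGD (rapid recovery gene
downregulation) genes are those induced at least 3-fold after 30 min of
high light, subcategorised by when they decline (category 3 during late HL,
category 2 during recovery, category 1 not at all); the decline criterion
is a 1.5-fold drop, a configurable stand-in since the original category
definitions live in earlier work. Category-wise RPL fold-change shifts are
compared with a two-sided Wilcoxon rank-sum test (exact below 8
observations per group when untied, tie-corrected normal approximation
otherwise).

## What the synthetic-data generator emulates

Every stage is validated against a generator with known ground truth
(`sim_config()`, `generate_truth()`, `simulate_decay_course()`,
`simulate_polysome_course()`):

* gene-wise exponential decay in the cordycepin arm from the baseline
  timepoint, half-lives log-uniform on [5, 200] min;
* a reference class (5% of genes) with half-lives of 1500–6000 min drawn
  from a high-abundance, low-variance stratum, mirroring the housekeeping
  transcripts the normalization depends on;
* the compositional artifact: per-sample relative abundances are
  renormalised to sum to one *before* counts are drawn;
* negative-binomial counting noise (dispersion 0.05 by default),
  gene-by-batch log-normal effects (SD 0.1) and log-normal library sizes
  (mean 3×10⁶, CV 0.2) — dispersion and replicate variance are conventional
  RNA-seq values, not fitted to any particular dataset, and the library
  size is scaled to the simulated gene count;
* condition-dependent stability: under HL a transcript-specific subset
  (default half of the non-reference genes, RRGD genes preferentially) has
  its half-life multiplied by `hl_destab_shift` (default 0.7); REC
  half-lives equal US, so destabilisation is transient. A subset rather
  than the whole transcriptome is shifted because destabilisation is
  observed to be transcript-specific, and because under an all-genes
  proportional shift the median-difference classification rule saturates at
  ~50% recall by construction, which would make recovery of the truly
  shifted set untestable;
* RRGD induction profiles (default 8-fold) and true RPL trajectories,
  including a late-HL translational shift in a fraction of genes that
  decouples total and polysome fold changes and recouples them during
  recovery;
* an optional per-gene lag during which decay is deferred (default 0),
  a hook for modelling residual transcriptional inertia immediately after
  inhibition.

All randomness derives from one seed through stream-specific sub-seeds, so
truth generation, count sampling and the polysome arm are independently
reproducible.

The generator does **not** simulate reads, UMIs, splicing/pre-mRNA signal,
gene–gene correlation, or amplification artifacts, and the mock arm's RRGD
trajectories are idealised piecewise-exponential curves. Passing the
recovery tests therefore demonstrates correctness of the estimation chain
under the stated noise model, not robustness to every failure mode of real
libraries.

## Problem sizes and observed behaviour

The standard validation course uses 2,000 genes, timepoints 10/20/30 min,
4 replicates in 2 batches and NB dispersion 0.05. Under these conditions
the pipeline (selection → factors → normalization → exclusion → fitting →
filtering) models roughly half the genes, with a median relative half-life
error near 11% and Spearman correlation with truth around 0.96; the
HL-vs-US bootstrap median difference is reliably negative with a 95% CI
excluding zero, and about 70% of the truly shifted genes are called
destabilised. The baseline-omission sensitivity analysis is run on a denser
course (0/7.5/15/30/60/120 min) because omitting the first of only three
timepoints leaves a two-point design; on the dense course omitting $t_0$
reduces the modelled-gene count slightly while half-lives of commonly
modelled genes correlate at $r \approx 0.99$. These numbers are recomputed,
not asserted, by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`.

## Known limitations

* Library-size (CPM) scaling replaces trimmed-mean normalization
  throughout; with decay-factor normalization layered on top the
  difference is absorbed into the factors, but raw CPM values are not
  TMM-comparable across samples.
* The detection filter operates on gene-level TPM; equivalence with
  transcript-level summaries produced by upstream quantifiers is not
  attempted.
* Random-effect structure is intercept-only; random slopes are not
  identifiable with two batches and three timepoints.
* The bootstrap treats genes as exchangeable units and ignores estimation
  error in each gene's half-life.
* With only two batches the mixed model is frequently singular and the OLS
  fallback dominates; this is recorded per gene in `fit_method`.
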