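# decaylab

Genome-wide mRNA half-life estimation from transcription-inhibition
time courses, for RNA biologists studying how transcript stability shifts
between stress conditions (e.g. high-light stress and recovery in plants).

After transcription is halted with an inhibitor such as cordycepin, each
transcript's abundance decays at its intrinsic first-order rate

    C(t) = C(t0) * exp(-kd * (t - t0)),    t1/2 = ln(2) / kd

but RNA-seq only measures *relative* abundance: as the RNA pool shrinks,
stable transcripts appear induced (the compositional artifact). decaylab
implements the full chain needed to turn such time courses into vetted,
comparable half-lives:

- **Decay-factor normalization** — reference genes (abundant, low-variance
  in mock samples: >= 95th percentile log2 CPM, <= 25th percentile CV) whose
  mean fold change in inhibitor-treated samples measures the pool
  shrinkage; fractional abundances are rescaled by this factor and genes
  still apparently induced (>= 1.5-fold) are excluded.
- **Gene-wise log-linear decay fits** — `ln(C/C_first) ~ time` with a
  random intercept per experimental batch (lme4), OLS fallback on singular
  fits, Wald test of the time coefficient, conditional R², and filters
  `p < 0.05`, `kd > 0`, `t1/2 <= 1440 min`.
- **Estimation statistics for condition contrasts** — paired mean/median
  differences and Cliff's delta with 10,000 bootstrap resamples;
  median-difference classification of destabilised/stabilised transcripts;
  cross-study comparison against external half-life tables.
- **Translation analysis** — relative polysome loading (RPL =
  polysome RPKM / total RPKM), 1.5-fold change grids of total mRNA vs RPL,
  RRGD (rapid recovery gene downregulation) categories and category-wise
  rank-sum comparisons, and percent-attenuation arithmetic for inhibitor
  efficacy.
- **A synthetic-data generator** with known ground truth (exponential
  decay, stable references, NB noise, batch effects, the compositional
  artifact, condition-dependent half-life shifts, RRGD and RPL
  trajectories) so that the entire pipeline is testable without any
  external download.

## Worked example

```r
library(decaylab)
demo_pipeline(seed = 7)
```

simulates a 500-gene mock/cordycepin course under unstressed (US) and
high-light (HL) conditions, normalizes it, fits every gene and contrasts
the conditions. It prints:

```
US: 292 genes modelled, median half-life 15.0 min
HL: 332 genes modelled, median half-life 13.6 min
HL - US paired median difference: -1.79 min [-2.28, -1.45]
131 of 262 common genes called destabilised under HL
```

"Modelled" genes are those whose decay fit passes all vetting filters. The
negative paired median difference with a bootstrap CI excluding zero shows
the simulated HL destabilisation (true half-life shift ×0.7 in half the
genes) is recovered, and the median-difference rule then labels individual
transcripts. Stage outputs (reference genes, decay factors, per-gene fits,
effect sizes, stability calls, manifest) are written as TSV/JSON to the run
directory.

The same machinery answers smaller questions directly:

```r
fit_decay(c(1, 0.5, 0.25), c(0, 10, 20))$halflife_min  # 10 (exact series)
attenuation_percent(375, 4.5)                          # 98.8 (% attenuation)
cliffs_delta(c(1, 3), c(2, 4))                         # -0.5
change_ratio(25.9, 7.7)                                # 3.4 ("3.4:1")
```

## Documentation

The methods vignette (`vignettes/halflife-methods.Rmd`) describes the
model and its assumptions, every tunable with its default and rationale,
what the synthetic generator does and does not emulate, and known
limitations.
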