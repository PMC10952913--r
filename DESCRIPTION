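Package: decaylab
Title: Genome-Wide mRNA Half-Life Estimation from Transcription-Inhibition
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating transcriptome-wide mRNA half-lives from
    RNA-seq time courses collected after chemical transcription inhibition
    (e.g. cordycepin), with support for stress/recovery designs. Implements
    reference-gene based decay-factor normalization to correct the
    compositional artifact of a shrinking RNA pool, gene-wise log-linear
    (mixed-effects) exponential-decay fitting with vetting filters,
    bootstrap estimation statistics (paired mean/median differences and
    Cliff's delta) for condition contrasts and cross-study comparisons,
    relative polysome loading analysis for paired total/polysome libraries,
    and a negative-binomial synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
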