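Package: slpairs
Title: Synthetic-Lethality Candidate Screening from Paired Expression, IHC and Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated screen for candidate synthetic-lethal (tumor-dependent)
    gene pairs in cancer cohorts. Sifts literature gene pairs by the four
    co-differential-expression patterns of paired tumor versus matched-normal
    log-ratios with a label-exchange permutation null and Storey q-value FDR
    control; tests paired dichotomized immunohistochemistry markers against
    dichotomized clinical features for synergistic and putative synergistic
    correlation by Fisher's exact test; expands candidates by the 2-hop
    synthetic-lethality rule; evaluates prognostic markers by Kaplan-Meier,
    Mantel-Haenszel log-rank and stepwise-AIC Cox proportional-hazards models
    with collinearity screening; and trains transferable proportional-hazards
    risk models scored by the hazard ratio of the risk score and the
    Gonen-Heller concordance probability estimate. A synthetic-cohort generator
    with planted co-expression patterns, interaction-only marker-phenotype
    associations and marker-dependent hazards makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
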