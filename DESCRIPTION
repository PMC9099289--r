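Package: xmsynergy
Title: Synergistic Genotype-Combination Analysis of Xenobiotic-Metabolism
    Polymorphisms in Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a candidate-gene case-control
    analysis pipeline for polymorphisms of xenobiotic-metabolizing enzymes
    (cytochromes P450, esterases, glutathione S-transferases) and Parkinson's
    disease risk. Provides Hardy-Weinberg equilibrium screening, single-locus
    association under genotypic, allelic, dominant, recessive and log-additive
    models with age/sex-adjusted logistic regression, genotype dichotomization,
    within-enzyme-class genotype-combination scans, and backward-elimination
    discovery of core synergistic genotype patterns, together with a
    synthetic-cohort generator that emulates the study's control genotype
    frequencies and demographics so the whole pipeline is testable without
    access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
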