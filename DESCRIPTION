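Package: sigqtl
Title: Phenological Synchrony Indices and QTL Mapping for Sequential-Seeding Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing reproductive synchrony in staggered plant
    cohorts and its genetic architecture. Implements a photothermal-unit
    (PTU) phenology engine that accumulates daylight degree-days above a
    base temperature, the SIg synchronization index (the log2 ratio of the
    between-cohort variance of germination timing to that of a later life
    event), and a single- and two-locus QTL genome scan for biparental
    recombinant inbred lines: Haley-Knott regression on conditional
    genotype probabilities, permutation-based genome-wide thresholds,
    Bayesian credible intervals for peak location, multi-QTL variance
    decomposition, and an additive/epistatic pair scan. A synthetic-data
    module generates sequential-seeding cohort phenology and RIL
    genotype/phenotype datasets with known truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
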