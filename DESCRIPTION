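Package: wormscreen
Title: Simulation and Statistics for Forward Genetic Suppressor Screens in
    Caenorhabditis elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing forward genetic suppressor
    screens in Caenorhabditis elegans. Provides an exact and stochastic
    Mendelian transmission engine with hermaphrodite selfing, male crosses,
    X/O sex determination and recombination; simulators for EMS mutagenesis,
    F2 selection and F1 clonal screen designs, and backcross dilution of
    background mutations; estimators of per-gene mutation frequency from
    screen yields with effective-genome accounting and exact Poisson
    intervals; a transgene rescue odds-ratio statistic with a delta-method
    standard error and chi-squared inference; two-point linkage mapping with
    exact binomial tests and Clopper-Pearson recombination bounds; and
    growth-rate and pharyngeal pump-rate phenotype models including a
    two-factor epistasis test. Seeded synthetic-data generators make every
    estimator testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
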