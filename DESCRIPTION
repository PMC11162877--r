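Package: adnakit
Title: Population-Genetic Analysis of Low-Coverage Ancient DNA Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the population-genetic analysis of ancient DNA
    together with modern reference panels: pseudo-haploid genotyping from
    read pileups, transition masking, EIGENSTRAT and PLINK text input and
    output, site filtering and dataset merging, LD pruning, outgroup f3
    shared-drift statistics and pairwise-mismatch diversity with weighted
    block-jackknife standard errors, projection principal component
    analysis for samples with missing data, window-based runs of
    homozygosity, a drift-based likelihood-ratio test of population
    continuity, coverage-ratio molecular sex determination and
    presence/absence genotyping of insertions from breakpoint-spanning
    reads. A synthetic-data generator with recorded ground truth supports
    verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
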