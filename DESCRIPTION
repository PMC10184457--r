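Package: oakniche
Title: Climatic Niche Evolution Analysis for Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying climatic and biotic niche evolution on
    time-calibrated phylogenies, motivated by analyses of Eurasian cork
    and holly oaks. Implements grid-weighted Koeppen-Geiger climate
    profiles from species occurrence records and their binning into
    five ordinal niche categories; grafting of fossil tips onto dated
    trees as sister lineages anchored at the fossil's oldest possible
    age; equal-rates Mk (Mk1) likelihood, maximum-likelihood rate
    estimation and marginal ancestral-state reconstruction with and
    without fossil information; Patterson's D-statistic (ABBA-BABA)
    with a locus bootstrap; and neighbour-net circular split networks
    on Hamming distances for categorical trait matrices. A synthetic
    data layer generates every input the pipeline consumes (birth-death
    trees, Mk-evolved characters, mosaic climate grids with clustered
    occurrences, multinomial ABBA/BABA site patterns, fossils with
    uniform age ranges) so all stages can be exercised and validated
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
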