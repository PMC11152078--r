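Package: balsel
Title: Forward Simulation and Detection Power Analysis for Balancing Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time diploid Wright-Fisher simulation of a balanced
    polymorphism maintained by negative frequency-dependent selection, on
    neutral or human-like exon/intron/intergenic chromosomes with discrete
    distributions of fitness effects, piecewise demography, multi-deme
    migration, and per-kilobase mutation and recombination rate maps.
    Includes re-implementations of site-frequency-spectrum based
    (composite likelihood ratio, B2-style) and linkage based (integrated
    haplotype score, iHS) scans for balancing selection, windowed summary
    statistics (nucleotide diversity, Tajima's D, haplotype diversity,
    mean D'), and the windowed ROC protocol used to quantify temporal
    detection power, plus establishment-probability and population
    structure false-positive experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
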