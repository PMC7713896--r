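Package: skimer
Title: Alignment-Free Evolutionary Distances and Phylogenies from MinHash Genome Sketches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates uncorrected p-distances between unaligned genome
    assemblies from bottom-sketch MinHash signatures of canonical k-mers,
    transforms them into proper evolutionary distances under the Poisson
    correction and the equal-input (F81) model with optional Gamma rate
    heterogeneity, and reconstructs distance-based phylogenies by
    neighbor-joining followed by ratchet-accelerated balanced
    minimum-evolution hill climbing.  Includes a GTR(+Gamma) sequence
    simulator with indel events for validating the distance transformations,
    least-squares fitting of the Gamma-shape equivalence parameter, and the
    accuracy statistics (through-origin regression slope, Fisher-z
    correlation thresholds, topology recovery rates) used to benchmark
    sketch-based distance estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
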