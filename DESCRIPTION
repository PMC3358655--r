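Package: prego
Title: Reconstructing Rearranged Cancer Genomes from Paired-End Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the block organization and integer copy numbers of a
    rearranged (cancer) genome from a reference-genome interval partition, a set
    of novel adjacencies derived from clustered discordant read pairs, and
    per-interval concordant read depths. Builds the interval-adjacency graph,
    infers maximum-likelihood integer edge multiplicities under a Poisson
    read-depth model subject to copy-number balance constraints (solved exactly
    by dynamic programming), extracts alternating Eulerian tours that spell
    block reconstructions of the rearranged genome, classifies variant edges
    (deletions, tandem duplications, inversions, translocations, inverted-repeat
    loops; reciprocal vs non-reciprocal; trivial pairs), and includes a
    deletion-genome simulator with contamination and depth-noise error models
    for robustness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
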