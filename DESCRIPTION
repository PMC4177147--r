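Package: coalexp
Title: Coalescent Inference of Single-Expansion Demography from
    Y-Chromosome Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a four-parameter single-expansion demographic model to
    rooted haplogroup phylogenies with SNP-count branch lengths. Simulates
    male-lineage genealogies under a variable-size Kingman coalescent,
    summarises trees by the singleton/shared-variant ratio and the mean and
    standard deviation of pairwise coalescence depths on length-normalised
    trees, and searches a sequentially refined parameter grid for scenarios
    minimising the average normalised delta (AND) between simulated and
    observed statistics. Includes synthetic-data generators emulating the
    contrasting star-like European R1b and bifurcating African E1b1a
    Y-chromosome expansions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
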