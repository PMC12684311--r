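Package: gfchrono
Title: Temporal Gene-Flow and Demography from Pool-Seq Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the timing of gene-flow disruption between
    fragmented populations from pooled whole-genome resequencing data.
    Includes pooled-VCF site filtering, Nei nucleotide diversity, pairwise
    Fst, folded and joint site frequency spectra, isolation-by-distance
    regression and UPGMA clustering; a two-deme structured-coalescent
    simulator with piecewise migration and population size; composite
    likelihood fitting of a nested two-epoch isolation-with-migration model
    over a grid of epoch breakpoints; deconvolution of time-integrated
    gene-flow estimates into per-interval rates with bootstrap confidence
    bands; aggregation of step-function effective-population-size
    trajectories; and generators for fully synthetic test data with known
    demographic truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
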