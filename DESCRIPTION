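Package: petdecon
Title: Blind Deconvolution of Protein Occupancy and Interaction Calling from
    ChIA-PET Read Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates marginal and joint RNA Polymerase II occupancy from
    ChIA-PET read pairs and calls high-resolution interactions between anchor
    locations (such as transcription start sites) and distal regions.
    Self-ligation read pairs are separated from inter-ligation pairs with a
    distance mixture model, the read spread function induced by sonication is
    recovered together with the occupancy distribution by Richardson-Lucy
    blind deconvolution, and candidate jointly occupied regions are scored
    with an exact binomial Pr(Y > Z) test corrected for sequencing
    undersampling through a missing-mass fixed point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
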