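Package: conncog
Title: White-Matter Connectome Efficiency, Psychometric Factors, and Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking structural brain-network organisation to
    general cognitive ability and educational attainment in children. Builds
    fractional-anisotropy-weighted connectomes from streamline-count and FA
    matrices, computes weighted nodal and global efficiency across a range of
    proportional density thresholds with area-under-curve aggregation, derives
    latent cognitive and attainment factors by maximum-likelihood exploratory
    factor analysis with Horn-style parallel analysis, and estimates the
    mediation of the efficiency-attainment relationship by general cognitive
    ability with bootstrap confidence intervals. Includes a synthetic-cohort
    generator with the assumed causal and factor structure so the whole
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
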