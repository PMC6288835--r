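Package: mvqtlmap
Title: Mean-Variance QTL Mapping for Experimental Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scan engine for mean-variance quantitative trait locus
    (QTL) mapping in F2 intercrosses. Jointly models genotype effects on the
    phenotype mean and on the log residual standard deviation with a double
    generalized linear model (DGLM), tests each locus for mean (mQTL),
    variance (vQTL), and joint (mvQTL) effects alongside the traditional
    standard-linear-model scan, and converts scan statistics to
    family-wise-error-rate-adjusted p-values via structured permutations and
    generalized-extreme-value tail fitting. Includes a hidden-Markov-model
    genotype-probability calculator with the Haldane map function, phenotype
    transformations (rank-based inverse normal, Box-Cox), an F2 cross
    simulator, and power comparison of the DGLM against the standard linear
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
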