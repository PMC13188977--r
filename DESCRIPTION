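Package: DTH
Title: Distance-Based Tests of Homogeneity of Multivariate Dispersions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonparametric permutation tests for homogeneity of multivariate
    dispersions based on pairwise dissimilarities. The main test (DTH) compares
    the full empirical distributions of within-group dissimilarities between
    groups using combined Kolmogorov-Smirnov and 1-Wasserstein statistics, so
    it is sensitive to arbitrary differences in the distribution of dispersions,
    not only to differences in mean dispersion. Also provides two classical
    comparators (a Levene-type test on distances to group centroids after
    principal-coordinates embedding, and a permutation test on mean squared
    within-group dissimilarities), negative-binomial and normal scale-mixture
    simulators for count and continuous multivariate data, Monte-Carlo
    size/power study drivers, readers for feature tables and square or
    lower-triangular distance matrices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    vegan,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
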