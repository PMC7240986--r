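Package: phycor
Title: Phylogenetically-Corrected Correlations of Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects coevolution of gene expression across species with a
    bivariate Brownian-Motion phylogenetic comparative method. Fits the
    evolutionary rate matrix of a gene pair on a time-calibrated phylogeny,
    optionally with replicate-based measurement error, and reports the
    phylogenetically-corrected correlation rho_C together with a
    likelihood-ratio test against independent evolution. Also provides
    cross-species TPM normalization to a standard lognormal scale, a
    Brownian-Motion assumption screen based on phylogenetic independent
    contrasts, weighted Spearman statistics for pair-level predictors,
    non-phylogenetic significance procedures (histogram-crossover cutoff and
    randomization p-values with FDR-calibrated cutoffs), Markov clustering of
    weighted interaction networks with a phylogenetically-corrected
    covariance-ratio modularity test, and a simulation harness that compares
    detection methods by TPR, FPR, FDR and accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
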