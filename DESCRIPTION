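Package: coaldelim
Title: Coalescent Species Delimitation with GMYC and Guided Multispecies-Coalescent rjMCMC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for coalescent-based species delimitation on multilocus
    data. Implements single-threshold generalized mixed Yule-coalescent (GMYC)
    fitting on ultrametric gene trees with likelihood-ratio testing and
    confidence sets; guided Bayesian species delimitation under the
    multispecies coalescent by reversible-jump MCMC over collapse/split models
    on a guide tree, with analytic inverse-gamma integration of the
    population-size parameters and a prior-sensitivity grid; an exhaustive
    posterior oracle for small guide trees; a censored-coalescent synthetic
    data generator (species trees, gene trees, JC69 alignments, categorical
    traits); and an integrative-evidence stage (partition concordance,
    trait-association permutation tests, and a conservative
    supported-under-all-priors rule).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
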