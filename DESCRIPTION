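Package: hapnet
Title: Hierarchical Haplotype Network Models on a Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical modelling of haplotype effects using phylogenetic
    relationships encoded as a directed acyclic graph. Implements a stationary
    first-order autoregressive Gaussian Markov random field over the haplotype
    phylogeny (the haplotype network model), with sparse precision matrices built
    directly from the graph, penalised-complexity priors for standard deviations
    and for the autocorrelation with base model at one, exact-Gaussian Bayesian
    inference with numerical integration over hyper-parameters, simulators for
    phylogenies, haplotype effects and phenotypes, and model comparison with the
    continuous ranked probability score.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
VignetteBuilder: knitr
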