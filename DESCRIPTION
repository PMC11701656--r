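Package: coupnet
Title: Bin-Free Naive Bayesian Inference of Functional Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers functional association (coupling) networks between
    proteins by bin-free naive Bayesian integration of heterogeneous
    omics evidence against multiple gold standards. Likelihoods of raw
    evidence scores are modelled with Gaussian kernel density estimates,
    log-likelihood ratios are summarised as low-degree polynomials,
    redundant datasets are down-weighted sequentially, and the final
    Bayesian score of every gene pair is calibrated to a positive
    predictive value with a logistic fit against gold-standard links.
    Includes evidence scoring for ten data types, orthology-based
    evidence and network transfer between species, network search
    algorithms (group, independent, MaxLink), EASE pathway enrichment,
    and a random-walk-with-restart benchmark against degree-preserving
    network nulls. A synthetic-data module generates worlds with planted
    couplings so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    minpack.lm,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
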