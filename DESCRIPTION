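Package: mvlogic
Title: Multi-Valued Logical Modeling of Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generalized multi-valued discrete (Thomas) modeling of signed,
    thresholded regulatory networks. Provides the logical image function over
    contextual K parameters, three update schemes (synchronous, fully
    asynchronous, and an asynchronous priority-class scheme with residual
    update memory), exhaustive state-transition-graph construction with
    attractor (terminal strongly connected component) and basin detection,
    feedback-circuit enumeration with functionality testing and exhaustive
    K-parameter tuning against qualitative behavior constraints, and a
    single-fault stochastic model with Monte Carlo estimation of
    attractor-to-attractor transition matrices evolved as Markov chains.
    Ships executable models of the hypothalamic-pituitary-adrenal (HPA) axis
    at rest, under persistent stress, and under glucocorticoid-receptor
    blockade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
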