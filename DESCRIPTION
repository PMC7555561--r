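Package: rlca
Title: Regularized Latent Class Analysis with Fused Penalties
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Penalized EM estimation of exploratory latent class models for
    dichotomous and polytomous item responses. Pairwise fused and fused-group
    LASSO, SCAD and MCP penalties on the item logits merge response
    probabilities across latent classes and/or response categories. Includes
    model selection over regularization-parameter grids by AIC/BIC with
    unique-parameter counting, regularization paths, partial-order (hierarchy)
    analysis of the fitted classes, distractor-frequency recoding of
    multiple-choice data, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
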