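Package: gengrad
Title: Perceptual and Value-Based Models of Aversive Generalisation Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level computational modelling of aversive generalisation
    gradients on personalised stimulus continua. Implements perceptual
    (stimulus-misidentification), value-transfer (Gaussian or monotonic
    kernel), and hybrid generative models of bounded expectancy ratings; a
    censored-normal mixture likelihood with DIRECT-L global optimisation and
    multistart refinement; BIC model comparison; a weighted up-down staircase
    simulator for perceptual titration; a synthetic-cohort generator emulating
    the full task design; and model/parameter recovery protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nloptr,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
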