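Package: voxfuse
Title: Voice Biomarkers and Contrastive Speech Embeddings for Parkinson's Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for multi-modal voice-based Parkinson's
    disease screening. Extracts perturbation-based acoustic biomarkers
    (fundamental frequency statistics, jitter, shimmer, harmonics-to-noise
    ratio, mel-frequency cepstral coefficients) from sustained phonation,
    learns self-supervised utterance embeddings with an NT-Xent contrastive
    objective, fuses both modalities in a residual-attention neural
    classifier, and interprets fitted models with mean-decrease-in-impurity
    and sampling-based Shapley attribution. Ships a synthetic-phonation
    generator with known per-cycle ground truth so the whole pipeline is
    testable without clinical audio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
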