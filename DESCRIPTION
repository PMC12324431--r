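Package: minscfg
Title: Minimal Stochastic Context-Free Grammars for RNA Secondary Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the minimal stochastic context-free grammars G6 (21
    free parameters) and G5 (20 free parameters) for RNA secondary
    structure. Provides a numerically stable log-space Inside algorithm
    with exact analytic gradients (via the Outside algorithm), enabling
    gradient-descent training of the grammar parameters from RNA
    sequences alone, without structures or alignments. Also provides
    maximum-likelihood training from labelled structures, base-pair
    posterior computation, maximum expected accuracy (MEA) and CYK
    structure decoding, base-pair level evaluation (sensitivity, PPV,
    global F1), composition-preserving sequence shuffling, and a
    generative sampler that draws (sequence, structure) pairs from any
    grammar parameterization. A command-line interface ties the pieces
    into reproducible train/predict/evaluate/sample pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    withr,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
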