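Package: vosshog
Title: Mutation Class Prediction from Voss-Encoded DNA with Gradient and
    Texture Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies nucleotide sequences into six somatic-mutation
    classes (normal, EGFR deletion/substitution, KRAS substitution, TP53
    deletion/substitution). Sequences are encoded as 4 x N binary indicator
    images (Voss mapping), summarised by fixed-length histogram-of-oriented-
    gradients (HOG) or local-binary-pattern (LBP) descriptors, and classified
    with multilayer perceptrons trained by scaled conjugate gradients (single
    or bagged with plurality voting) or one-against-all kernel support vector
    machines (single or bucket-of-models). Includes a seeded synthetic corpus
    generator emulating the structure of an NSCLC mutation benchmark so the
    whole pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
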