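Package: abcontext
Title: Context-Vector Augmented ABC Literature-Based Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers candidate drug-disease relationships from biomedical
    abstracts with Swanson's ABC model augmented by per-interaction context
    vectors. Provides dictionary-based multi-level entity tagging (gene,
    drug, disease, symptom), sentence-level drug-gene and gene-disease
    co-occurrence extraction, averaged context-term vectors per interaction,
    cosine and Spearman context similarity, bridge-gene scoring (baseline,
    sum, max, hybrid), precision-at-k evaluation against a gold-standard
    pair set, and a synthetic-world generator with planted coherent and
    decoy chains for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
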