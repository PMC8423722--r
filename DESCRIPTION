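Package: abbrevx
Title: Ontology-Aware Disambiguation of Clinical Abbreviations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Resolves ambiguous abbreviations in clinical notes to their
    intended long forms. Training data are generated by reverse
    substitution (replacing written-out expansions with their
    abbreviation) and augmented with sentences of nearby concepts from a
    medical ontology, sampled through a temperature softmax over
    embedding-space distances. A small convolutional encoder combines the
    local token window with an IDF-weighted global note context and
    classifies by dot product against learned expansion embeddings;
    concept embeddings can be pretrained as ancestor sums over the
    ontology. Includes subword skip-gram embedding training, a
    tree-structured Parzen estimator for the sampling temperature,
    micro/macro accuracy scoring with bootstrap resampling and one-sided
    Wilcoxon signed-rank model comparison, and a synthetic corpus and
    ontology generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
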