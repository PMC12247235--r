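Package: medbias
Title: Measuring Demographic Bias in Healthcare Word Embeddings with WEAT and SD-WEAT
Version: 0.1.0
Authors@R:
    person("medbias", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting and measuring demographic bias in the word
    embeddings used by healthcare and biomedical language models. Implements
    the Word Embedding Association Test (WEAT) -- cosine-based association
    scores, a standardized effect size, and an exhaustive or Monte-Carlo
    permutation p-value -- together with SD-WEAT, a multi-class extension
    that pools all attribute words, repeatedly draws small random attribute
    pairs, and summarizes bias as the standard deviation of the resulting
    effect sizes. Ships a benchmark-dataset format for gender- and
    ethnicity-linked medical-condition term sets (with bundled fixtures),
    loaders for GloVe and word2vec text vector tables with mean pooling of
    multi-word terms, pairwise multi-group analysis, an attribute-word
    importance procedure, a synthetic embedding generator with planted bias
    for calibration and power studies, and table-style report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
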