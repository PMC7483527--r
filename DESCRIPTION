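Package: emovoc
Title: Active Emotion Vocabulary Scoring for Natural Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the richness of the emotion vocabulary a writer
    actively uses in natural text. Scores each document for the number of
    unique, lemma-collapsed emotion words per 100 tokens (overall and for
    sadness, fear, anger, undifferentiated-negative and positive families),
    alongside frequency-based category rates, an open-class type/token
    ratio, and length/coverage document screening. Includes Pearson and
    partial correlation machinery with bias-corrected and accelerated
    (BCa) bootstrap confidence intervals, split-half and test-retest
    reliability over a scored corpus, and a synthetic corpus generator
    with known latent author parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    jsonlite
Config/testthat/edition: 3
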