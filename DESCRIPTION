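Package: vaxtalk
Title: Cross-Platform Analysis of Vaccine Discourse on Social Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing vaccine-related discourse across social media
    platforms. Provides a comment-corpus model with top-comment selection and
    summary statistics, a text preprocessing pipeline (markup stripping,
    pluggable translation, token normalization, lemmatization), Krippendorff's
    alpha for interrater reliability of manual category coding, lambda-weighted
    term-relevance keyword extraction per category, cosine similarity of
    per-platform anti-vaccine category distributions, chi-square homogeneity
    testing with zero-expected-cell pruning and Bonferroni post-hoc pairwise
    comparisons, and a seeded synthetic corpus generator that emulates the
    statistical structure of annotated top-comment data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
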