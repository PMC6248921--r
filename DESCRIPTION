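Package: natlex
Title: Diagnostic Vocabulary and National-Stereotype Profiles from Two-Corpus
    Text Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for finding words, emojis and emoticons that are
    statistically over-represented in one text corpus relative to another
    using the weighted log-odds ratio with an informative Dirichlet prior,
    and for relating the resulting diagnostic lexica to positivity norms
    and to Big Five facet rating profiles. Includes tweet-style record
    filtering with content-based bot detection (pairwise longest-common-
    substring dissimilarity and URL rate), an emoji- and emoticon-aware
    tokenizer, decile binning of diagnostic vocabularies with valence
    lexicon comparisons, survey-rating cleaning and facet statistics
    (Welch tests, ICC(1,k), within-subject adjusted standard errors,
    difference-profile correlations), and a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    stringi,
    readr,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
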