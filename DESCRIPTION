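Package: infmetric
Title: Quantifying National Influence in Treaty Clause Dissemination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Influence (INF) metric for bilateral investment
    treaty corpora: each country's score in [0,1] summarises how strongly the
    clause texts of its treaties are re-used across the corpus. The pipeline
    covers clause-text preprocessing (tokenisation, stop-word removal,
    stemming or lemmatisation), TF-IDF vectorisation with cosine similarity
    over all treaty pairs, retrospective percentile-based threshold
    selection, and weighted-frequency aggregation of high-similarity
    documents per country. Includes a synthetic treaty-corpus generator with
    controlled clause-copying structure for validation, star-network hub
    detection, edge-list export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
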