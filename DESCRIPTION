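Package: specrec
Title: Self-Adaptive Telemedicine Specialist Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-based recommendation of telemedicine specialists from
    electronic medical record (EMR) text. Patient features are TF-IDF-weighted
    averages of skip-gram word embeddings; candidate specialists are retrieved
    by EMR cosine similarity, repaired for cold start with a weighted Jaccard
    similarity over long-term knowledge-attribute profiles, and extended at the
    semantic level with a collapsed-Gibbs LDA topic model and Jensen-Shannon
    similarity. Final rankings fuse a time-decayed specialist activity index,
    the professional recommendation index, and subjective and objective
    quality-of-service feedback. Includes a synthetic-world generator with
    known ground truth for end-to-end validation, and top-N evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
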