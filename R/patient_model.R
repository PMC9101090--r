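#' Train skip-gram word embeddings on a corpus
#'
#' Fits skip-gram-with-negative-sampling word vectors over the corpus
#' documents. Training is single-threaded with a private seeded RNG, so a
#' fixed seed reproduces the vectors exactly. Every vocabulary token receives
#' a vector (min_count is effectively 1).
#'
#' @param corpus a `specrec_corpus`, or a list of token vectors.
#' @param dimension embedding dimension p (default 100).
#' @param window maximum context window (default 5; the effective window per
#'   token is drawn uniformly from 1..window, as usual for skip-gram).
#' @param negative number of negative samples per context pair.
#' @param epochs passes over the corpus; the default of 30 suits desk-scale
#'   corpora (a few thousand short documents), where fewer passes leave all
#'   vectors sharing one dominant direction and cosine similarities
#'   saturated.
#' @param lr initial learning rate, decayed linearly.
#' @param seed integer RNG seed.
#' @return Object of class `specrec_embeddings`: list with `dimension`,
#'   `vectors` (V x p matrix, rownames = tokens) and `seed`.
#' @export
train_embeddings <- function(corpus, dimension = 100L, window = 5L,
                             negative = 5L, epochs = 30L, lr = 0.025,
                             seed = 1L) {
  docs <- if (inherits(corpus, "specrec_corpus")) corpus$documents else corpus
  stopifnot(length(docs) > 0, dimension >= 1)
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  if (length(vocab) < 1) stop("vocabulary is empty")
  ids <- lapply(docs, function(d) match(d, vocab) - 1L)
  M <- sgns_train(ids, length(vocab), as.integer(dimension),
                  as.integer(window), as.integer(negative),
                  as.integer(epochs), lr, as.integer(seed))
  rownames(M) <- vocab
  structure(list(dimension = as.integer(dimension), vectors = M,
                 seed = as.integer(seed)),
            class = "specrec_embeddings")
}

#' Term frequency-inverse document frequency weights
#'
#' tf(w, d) = count(w, d) / |d|; idf(w) = ln(N / df(w)); weight = tf * idf.
#' No smoothing: df >= 1 holds for every vocabulary token, and a token
#' occurring in all N documents gets idf 0.
#'
#' @param corpus a `specrec_corpus` or named list of token vectors.
#' @return Object of class `specrec_tfidf`: list with `n_docs`, `doc_freq`
#'   (named integer) and `weights` (named list, per doc a named numeric vector
#'   over its distinct tokens).
#' @export
tfidf_weights <- function(corpus) {
  docs <- if (inherits(corpus, "specrec_corpus")) corpus$documents else corpus
  stopifnot(length(docs) > 0)
  n_docs <- length(docs)
  distinct <- lapply(docs, unique)
  df <- table(unlist(distinct, use.names = FALSE))
  doc_freq <- stats::setNames(as.integer(df), names(df))
  idf <- log(n_docs / doc_freq)
  weights <- lapply(docs, function(d) {
    tf <- table(d) / length(d)
    stats::setNames(as.numeric(tf) * idf[names(tf)], names(tf))
  })
  structure(list(n_docs = n_docs, doc_freq = doc_freq, weights = weights),
            class = "specrec_tfidf")
}

# shared kernel: (1/f) * sum over distinct tokens of tfidf(w, d) * v_w
.doc_vector <- function(tokens, emb, w) {
  tokens <- unique(tokens)
  if (!length(tokens)) stop("cannot embed an empty document")
  missing <- setdiff(tokens, rownames(emb$vectors))
  if (length(missing))
    stop("token(s) without embedding: ", paste(missing, collapse = ", "))
  V <- emb$vectors[tokens, , drop = FALSE]
  drop(crossprod(V, w[tokens])) / length(tokens)
}

#' Document vector: TF-IDF-weighted embedding average
#'
#' The EMR feature vector is the average over the f *distinct* feature words
#' of the word vector scaled by its TF-IDF weight.
#'
#' @param doc_id document id present in `tfidf`.
#' @param tokens the document's token vector.
#' @param emb a `specrec_embeddings` model covering all tokens.
#' @param tfidf a `specrec_tfidf` table containing `doc_id`.
#' @return numeric vector of length `emb$dimension`.
#' @export
document_vector <- function(doc_id, tokens, emb, tfidf) {
  stopifnot(inherits(emb, "specrec_embeddings"),
            inherits(tfidf, "specrec_tfidf"))
  w <- tfidf$weights[[doc_id]]
  if (is.null(w)) stop("doc_id not in tf-idf table: ", doc_id)
  .doc_vector(tokens, emb, w)
}

#' Vectorize all corpus documents
#'
#' @param corpus a `specrec_corpus`.
#' @param emb embeddings covering the corpus vocabulary.
#' @param tfidf TF-IDF table built from the same corpus (built on the fly if
#'   omitted).
#' @return matrix (documents x dimension) with doc_id rownames.
#' @export
corpus_doc_vectors <- function(corpus, emb, tfidf = tfidf_weights(corpus)) {
  vecs <- vapply(names(corpus$documents),
                 function(id) document_vector(id, corpus$documents[[id]],
                                              emb, tfidf),
                 numeric(emb$dimension))
  t(vecs)
}

#' Vectorize a new (target) document against an existing corpus
#'
#' Term frequencies come from the target text itself; inverse document
#' frequencies from the reference corpus table. Tokens absent from the corpus
#' vocabulary are dropped (with a warning) since they have neither an
#' embedding nor a document frequency.
#'
#' @param tokens token vector of the target EMR.
#' @param emb corpus embeddings.
#' @param tfidf corpus TF-IDF table.
#' @return numeric vector of length `emb$dimension`.
#' @export
target_doc_vector <- function(tokens, emb, tfidf) {
  known <- tokens[tokens %in% names(tfidf$doc_freq) &
                    tokens %in% rownames(emb$vectors)]
  if (!length(known))
    stop("target document shares no vocabulary with the corpus")
  if (length(known) < length(tokens))
    warning(sprintf("dropped %d out-of-vocabulary target token(s)",
                    length(tokens) - length(known)))
  tf <- table(known) / length(known)
  idf <- log(tfidf$n_docs / tfidf$doc_freq[names(tf)])
  w <- stats::setNames(as.numeric(tf) * idf, names(tf))
  .doc_vector(known, emb, w)
}

#' Cosine similarity between two vectors
#'
#' @param a,b non-zero numeric vectors of equal length.
#' @return similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

# ---- candidate sets ---------------------------------------------------------

new_candidate_set <- function(df) {
  stopifnot(all(c("specialist_id", "ini_score", "provenance",
                  "short_score") %in% names(df)))
  if (anyDuplicated(df$specialist_id))
    stop("candidate set has duplicate specialist ids")
  structure(tibble::as_tibble(df), class = c("specrec_candidates",
                                             class(tibble::tibble())))
}

# total deterministic order: governing score descending, ids ascending
sort_candidates <- function(cs, by = "ini_score") {
  cs[order(-cs[[by]], cs$specialist_id), ]
}

#' Generate the initial recommended-specialist candidate set
#'
#' For every specialist, the initial recommendation index `ini_score` is the
#' highest EMR similarity between the target patient and any patient that
#' specialist has treated; specialists are ranked by `ini_score` and the
#' top `n` retained. No similarity threshold is applied (thresholding would
#' curtail recommendations for uncommon diseases).
#'
#' @param target numeric target document vector.
#' @param doc_vectors matrix of corpus document vectors (doc_id rownames).
#' @param doc_specialists named character vector mapping doc_id ->
#'   specialist_id.
#' @param n candidate-set size (default 10).
#' @return A `specrec_candidates` tibble sorted by `ini_score` descending,
#'   ties broken by specialist id; provenance `"patient-similarity"`.
#' @export
generate_candidates <- function(target, doc_vectors, doc_specialists,
                                n = 10L) {
  if (is.null(dim(doc_vectors)) || nrow(doc_vectors) == 0)
    stop("empty corpus: no document vectors")
  ids <- rownames(doc_vectors)
  stopifnot(!is.null(ids), all(ids %in% names(doc_specialists)))
  norms <- sqrt(rowSums(doc_vectors^2))
  if (any(norms == 0)) stop("zero document vector in corpus")
  tn <- sqrt(sum(target^2))
  if (tn == 0) stop("zero target vector")
  sims <- drop(doc_vectors %*% target) / (norms * tn)
  spec <- doc_specialists[ids]
  ini <- tapply(sims, spec, max)
  df <- tibble::tibble(specialist_id = names(ini),
                       ini_score = as.numeric(ini),
                       provenance = "patient-similarity",
                       short_score = NA_real_)
  df <- sort_candidates(df)
  new_candidate_set(utils::head(df, min(n, nrow(df))))
}
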