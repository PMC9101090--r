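#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Documents are bags of tokens; the sampler runs a fixed number of full
#' sweeps with a private seeded RNG (deterministic for a given seed). The
#' returned topic-word matrix `phi` (K x V) and document-topic matrix `theta`
#' (D x K) are the usual smoothed count estimates
#' `phi[k, w] = (n_kw + beta) / (n_k + V beta)` and
#' `theta[d, k] = (n_dk + alpha) / (n_d + K alpha)`.
#'
#' @param docs named list of token character vectors (one document per
#'   specialist in the short-term knowledge model).
#' @param K number of topics.
#' @param alpha document-topic Dirichlet hyperparameter; default 0.1, suited
#'   to short clinical documents whose topic mixtures are sparse (a large
#'   alpha of the 50/K kind overwhelms the ~20-token counts of an EMR and
#'   flattens every document-topic distribution toward uniform).
#' @param beta topic-word Dirichlet hyperparameter; default 0.01.
#' @param iterations Gibbs sweeps (default 500).
#' @param seed integer RNG seed.
#' @param vocabulary optional fixed vocabulary (defaults to the union of doc
#'   tokens).
#' @return Object of class `specrec_lda`: list with `K`, `alpha`, `beta`,
#'   `phi`, `theta`, `vocabulary`, `iterations`, `seed`, `n_tokens`.
#' @export
fit_lda <- function(docs, K, alpha = NULL, beta = 0.01, iterations = 500L,
                    seed = 1L, vocabulary = NULL) {
  if (K < 1) stop("K must be >= 1")
  stopifnot(length(docs) >= 1)
  if (is.null(names(docs))) names(docs) <- sprintf("doc%04d", seq_along(docs))
  if (is.null(alpha)) alpha <- 0.1
  if (is.null(vocabulary))
    vocabulary <- sort(unique(unlist(docs, use.names = FALSE)))
  ids <- lapply(docs, function(d) {
    i <- match(d, vocabulary)
    if (anyNA(i)) stop("document token outside vocabulary")
    i - 1L
  })
  fit <- lda_gibbs_fit(ids, length(vocabulary), as.integer(K), alpha, beta,
                       as.integer(iterations), as.integer(seed))
  V <- length(vocabulary)
  phi <- (fit$nkw + beta) / (fit$nk + V * beta)
  theta <- (fit$ndk + alpha) /
    (rowSums(fit$ndk) + K * alpha)
  colnames(phi) <- vocabulary
  rownames(phi) <- sprintf("topic_%d", seq_len(K))
  rownames(theta) <- names(docs)
  colnames(theta) <- rownames(phi)
  structure(list(K = as.integer(K), alpha = alpha, beta = beta, phi = phi,
                 theta = theta, vocabulary = vocabulary,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 n_tokens = fit$n_tokens,
                 topic_counts = fit$nk),
            class = "specrec_lda")
}

#' @export
print.specrec_lda <- function(x, ...) {
  cat("<specrec_lda> K =", x$K, "topics,", nrow(x$theta), "documents,",
      length(x$vocabulary), "terms\n")
  invisible(x)
}

#' Top words of each topic
#'
#' @param model a fitted `specrec_lda`.
#' @param n words per topic (default 10, the usual report size).
#' @return named list; per topic a named numeric vector of word
#'   probabilities, descending.
#' @export
top_words <- function(model, n = 10L) {
  stopifnot(inherits(model, "specrec_lda"))
  apply(model$phi, 1, function(p) {
    o <- order(-p)[seq_len(min(n, length(p)))]
    stats::setNames(p[o], colnames(model$phi)[o])
  }, simplify = FALSE)
}

#' Corpus perplexity of a fitted topic model
#'
#' `exp(-sum log P(w | d) / N)` with
#' `P(w | d) = sum_k theta[d, k] * phi[k, w]`; documents are matched to
#' `theta` rows by name.
#'
#' @param model a `specrec_lda` fit.
#' @param docs named list of token vectors over the model vocabulary; default
#'   the implied training documents cannot be recovered, so pass them.
#' @return perplexity, a real >= 1 for proper distributions.
#' @export
perplexity <- function(model, docs) {
  stopifnot(inherits(model, "specrec_lda"))
  if (is.null(names(docs))) names(docs) <- rownames(model$theta)
  if (!all(names(docs) %in% rownames(model$theta)))
    stop("document names not present in the fitted model")
  total_ll <- 0
  total_n <- 0
  pwd <- model$theta[names(docs), , drop = FALSE] %*% model$phi  # D x V
  for (i in seq_along(docs)) {
    idx <- match(docs[[i]], model$vocabulary)
    if (anyNA(idx))
      stop("token outside the model vocabulary in document ", names(docs)[i])
    total_ll <- total_ll + sum(log(pwd[i, idx]))
    total_n <- total_n + length(idx)
  }
  exp(-total_ll / total_n)
}

#' Select the number of topics by minimum held-out perplexity
#'
#' Fits the model for each K in the grid (same data, same seed) and returns
#' the K minimizing *document-completion* perplexity: each document's tokens
#' are split into alternating halves, the model (and hence its document-topic
#' distributions) is fitted on the first halves, and perplexity is evaluated
#' on the held-out halves. Perplexity measured on the tokens the sampler was
#' fitted to decreases monotonically with K (more topics always memorize
#' better), so it cannot locate the planted topic count; the completion form
#' penalizes the over-fitted splits and recovers the elbow. Ties go to the
#' smaller K. The full (K, perplexity) table is attached as attribute
#' `"perplexities"`.
#'
#' @param docs named list of token vectors (at least 2 tokens per document
#'   are needed for a document to contribute held-out mass).
#' @param k_grid ascending integer grid of candidate topic counts.
#' @param alpha,beta,iterations,seed passed to [fit_lda()]; `iterations`
#'   defaults to 200 here, enough for the perplexity ordering to stabilize.
#' @return the selected K (integer) with attribute `perplexities`.
#' @export
select_topic_count <- function(docs, k_grid, alpha = NULL, beta = 0.01,
                               iterations = 200L, seed = 1L) {
  if (!length(k_grid)) stop("empty topic-count grid")
  k_grid <- as.integer(k_grid)
  if (is.null(names(docs))) names(docs) <- sprintf("doc%04d", seq_along(docs))
  vocabulary <- sort(unique(unlist(docs, use.names = FALSE)))
  est <- lapply(docs, function(d) d[seq_along(d) %% 2L == 1L])
  held <- lapply(docs, function(d) d[seq_along(d) %% 2L == 0L])
  held <- held[lengths(held) > 0 & lengths(est) > 0]
  est <- est[lengths(est) > 0]
  if (!length(held))
    stop("documents too short for held-out topic-count selection")
  perp <- vapply(k_grid, function(K) {
    m <- fit_lda(est, K, alpha = alpha, beta = beta,
                 iterations = iterations, seed = seed,
                 vocabulary = vocabulary)
    perplexity(m, held)
  }, numeric(1))
  best <- k_grid[which.min(perp)]  # which.min takes the first, i.e. smaller K
  structure(best, perplexities = tibble::tibble(K = k_grid,
                                                perplexity = perp))
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' Base-2 logarithms, so the divergence lies in \[0, 1\]:
#' `D_JS = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`.
#'
#' @param p,q probability vectors of equal length, each summing to 1 (within
#'   1e-6).
#' @return divergence in \[0, 1\].
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("distributions differ in length")
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must be probability vectors summing to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  d <- kl(p, m) / 2 + kl(q, m) / 2
  min(max(d, 0), 1)  # clip floating-point spill at the boundaries
}

#' Topic-distribution similarity (1 - Jensen-Shannon divergence)
#'
#' The short-term knowledge similarity between two specialists' document-
#' topic distributions; 1 for identical distributions, 0 for disjoint
#' support.
#'
#' @inheritParams js_divergence
#' @return similarity in \[0, 1\].
#' @export
js_similarity <- function(p, q) 1 - js_divergence(p, q)

#' Per-specialist documents for the short-term knowledge model
#'
#' The LDA training corpus keys documents by specialist: each specialist's
#' document is the concatenation (in corpus order) of all EMRs they
#' diagnosed.
#'
#' @param corpus a `specrec_corpus`.
#' @return named list of token vectors, one per specialist id (sorted).
#' @export
specialist_documents <- function(corpus) {
  stopifnot(inherits(corpus, "specrec_corpus"))
  split_ids <- split(names(corpus$documents), corpus$meta$specialist_id)
  lapply(split_ids, function(ids)
    unlist(corpus$documents[ids], use.names = FALSE))
}

#' Extend the candidate set in topic space
#'
#' Every incoming member keeps (or receives) `short_score = 1`. Each member
#' acts as a seed: non-member specialists whose document-topic distribution
#' has Jensen-Shannon similarity `>= min_sim` to the seed (at most
#' `per_seed_cap` per seed, best first) are added with provenance
#' `"topic-extension"`, `short_score` = the similarity and `ini_score`
#' inherited from the seed. A specialist reachable from several seeds keeps
#' the assignment maximizing `ini_score * short_score`. Members are never
#' removed or down-scored.
#'
#' @param candidates a `specrec_candidates` set.
#' @param profiles matrix of document-topic distributions (specialist ids as
#'   rownames, one row per specialist; rows sum to 1).
#' @param min_sim similarity threshold (default 0.8).
#' @param per_seed_cap maximum additions per seed (default 10).
#' @return The extended `specrec_candidates` set.
#' @export
extend_candidates <- function(candidates, profiles, min_sim = 0.8,
                              per_seed_cap = 10L) {
  stopifnot(inherits(candidates, "specrec_candidates"))
  if (nrow(candidates) == 0) return(candidates)
  members <- candidates$specialist_id
  missing <- setdiff(members, rownames(profiles))
  if (length(missing))
    stop("no topic profile for candidate(s): ",
         paste(missing, collapse = ", "))

  out <- candidates
  out$short_score <- 1
  others <- setdiff(rownames(profiles), members)
  if (!length(others)) return(new_candidate_set(sort_candidates(out)))

  best <- list()  # per non-member: the best (ini, short) assignment
  for (i in seq_len(nrow(candidates))) {
    seed_id <- candidates$specialist_id[i]
    seed_ini <- candidates$ini_score[i]
    sims <- vapply(others, function(s)
      js_similarity(profiles[seed_id, ], profiles[s, ]), numeric(1))
    qual <- which(sims >= min_sim)
    if (!length(qual)) next
    qual <- qual[order(-sims[qual], others[qual])]
    qual <- utils::head(qual, per_seed_cap)
    for (k in qual) {
      id <- others[k]
      cand <- c(ini = unname(seed_ini), short = unname(sims[k]))
      prev <- best[[id]]
      if (is.null(prev) || cand["ini"] * cand["short"] >
          prev["ini"] * prev["short"])
        best[[id]] <- cand
    }
  }
  for (id in names(best)) {
    out <- tibble::add_row(out, specialist_id = id,
                           ini_score = unname(best[[id]]["ini"]),
                           provenance = "topic-extension",
                           short_score = unname(best[[id]]["short"]))
  }
  new_candidate_set(sort_candidates(out))
}
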