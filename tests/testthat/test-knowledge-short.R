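# two disjoint-vocabulary themes give a cleanly separable corpus
disjoint_docs <- function(n = 20, len = 30, seed = 2) {
  set.seed(seed)
  va <- sprintf("a%02d", 1:15)
  vb <- sprintf("b%02d", 1:15)
  docs <- lapply(1:n, function(i)
    sample(if (i %% 2 == 0) va else vb, len, replace = TRUE))
  names(docs) <- sprintf("d%02d", 1:n)
  docs
}

test_that("the Gibbs sampler is deterministic and returns proper distributions", {
  docs <- disjoint_docs()
  m1 <- fit_lda(docs, K = 3, iterations = 60, seed = 5)
  m2 <- fit_lda(docs, K = 3, iterations = 60, seed = 5)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$theta, m2$theta)
  expect_equal(unname(rowSums(m1$phi)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(m1$theta)), rep(1, length(docs)),
               tolerance = 1e-9)
  expect_true(all(m1$phi > 0) && all(m1$theta > 0))
  expect_error(fit_lda(docs, K = 0), "K")
})

test_that("token mass is conserved by the count tables", {
  docs <- disjoint_docs(n = 10)
  m <- fit_lda(docs, K = 4, iterations = 30, seed = 1)
  expect_equal(sum(m$topic_counts), m$n_tokens)
  expect_equal(m$n_tokens, sum(lengths(docs)))
})

test_that("a two-theme corpus separates at K = 2", {
  docs <- disjoint_docs(n = 20, len = 40)
  m <- fit_lda(docs, K = 2, iterations = 200, seed = 4)
  expect_true(all(apply(m$theta, 1, max) >= 0.9))
  # themes land on different topics
  lead <- apply(m$theta, 1, which.max)
  expect_equal(length(unique(lead[c(TRUE, FALSE)])), 1)
  expect_false(lead[1] == lead[2])
})

test_that("perplexity matches its closed forms", {
  # hand-built model putting probability 1 on each document's only word
  fake <- structure(list(
    K = 2L, alpha = 0.1, beta = 0.01,
    phi = rbind(topic_1 = c(w1 = 1, w2 = 0), topic_2 = c(w1 = 0, w2 = 1)),
    theta = rbind(d1 = c(1, 0), d2 = c(0, 1)),
    vocabulary = c("w1", "w2"), iterations = 0L, seed = 1L, n_tokens = 4L),
    class = "specrec_lda")
  expect_equal(perplexity(fake, list(d1 = rep("w1", 3), d2 = "w2")), 1)
  # uniform P(w|d) = 1/V -> perplexity V
  V <- 5
  unif <- structure(list(
    K = 1L, alpha = 0.1, beta = 0.01,
    phi = matrix(1 / V, 1, V, dimnames = list("topic_1",
                                              sprintf("w%d", 1:V))),
    theta = matrix(1, 2, 1, dimnames = list(c("d1", "d2"), "topic_1")),
    vocabulary = sprintf("w%d", 1:V), iterations = 0L, seed = 1L,
    n_tokens = 6L), class = "specrec_lda")
  expect_equal(perplexity(unif, list(d1 = c("w1", "w3"), d2 = "w5")), V)
  expect_error(perplexity(unif, list(d1 = "nope")), "vocabulary")
})

test_that("a two-theme corpus is better explained by K = 2 than K = 1", {
  docs <- disjoint_docs(n = 20, len = 40)
  p1 <- perplexity(fit_lda(docs, 1, iterations = 150, seed = 8), docs)
  p2 <- perplexity(fit_lda(docs, 2, iterations = 150, seed = 8), docs)
  expect_lt(p2, p1)
})

test_that("topic-count selection returns grid minima with smaller-K ties", {
  docs <- disjoint_docs(n = 30, len = 40)
  expect_equal(as.integer(select_topic_count(docs, 2L)), 2L)
  # duplicated grid value: identical perplexities, first (smaller index) wins
  sel <- select_topic_count(docs, c(2L, 2L), seed = 3)
  expect_equal(as.integer(sel), 2L)
  tab <- attr(sel, "perplexities")
  expect_equal(tab$perplexity[1], tab$perplexity[2])
  expect_error(select_topic_count(docs, integer()), "empty")
  full <- select_topic_count(docs, c(2L, 6L), seed = 3)
  expect_equal(as.integer(full), 2L)
})

test_that("Jensen-Shannon divergence matches closed forms and an independent oracle", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(js_divergence(p, p), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)
  # hand computation: p = (.5, .5), q = (1, 0); m = (.75, .25)
  d <- 0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25)) +
    0.5 * (1 * log2(1 / 0.75))
  expect_equal(js_divergence(c(0.5, 0.5), c(1, 0)), d, tolerance = 1e-12)
  expect_equal(d, 0.311278, tolerance = 1e-6)
  expect_equal(js_similarity(c(0.5, 0.5), c(1, 0)), 1 - d,
               tolerance = 1e-12)
  expect_error(js_divergence(c(0.5, 0.5), c(0.5, 0.5, 0)), "length")
  expect_error(js_divergence(c(0.7, 0.7), c(0.5, 0.5)), "summing")

  set.seed(21)
  for (i in 1:1000) {
    k <- sample(2:12, 1)
    a <- random_distribution(k); b <- random_distribution(k)
    m <- (a + b) / 2
    oracle <- sum(a * log2(a / m)) / 2 + sum(b * log2(b / m)) / 2
    expect_equal(js_divergence(a, b), oracle, tolerance = 1e-12)
    expect_equal(js_divergence(b, a), js_divergence(a, b),
                 tolerance = 1e-12)
    expect_true(js_divergence(a, b) >= 0 && js_divergence(a, b) <= 1)
  }
})

test_that("specialist documents concatenate that specialist's EMRs", {
  w <- small_world()
  corp <- build_corpus(w$consultations, w$dicts)
  sdocs <- specialist_documents(corp)
  for (s in names(sdocs)) {
    ids <- corp$meta$doc_id[corp$meta$specialist_id == s]
    expect_identical(sdocs[[s]],
                     unlist(corp$documents[ids], use.names = FALSE))
  }
})

test_that("topic-space extension adds near-identical profiles and respects thresholds", {
  profiles <- rbind(A = c(0.9, 0.1), B = c(0.88, 0.12), C = c(0.1, 0.9))
  cands <- toy_candidates(ids = "A", ini = 0.6)
  ext <- extend_candidates(cands, profiles, min_sim = 0.8)
  expect_setequal(ext$specialist_id, c("A", "B"))
  expect_equal(ext$short_score[ext$specialist_id == "A"], 1)
  b <- ext[ext$specialist_id == "B", ]
  expect_equal(b$provenance, "topic-extension")
  expect_equal(b$ini_score, 0.6)  # inherited from the seed
  expect_equal(b$short_score, js_similarity(profiles["A", ],
                                            profiles["B", ]))

  # identical profile: short_score exactly 1
  prof2 <- rbind(A = c(0.7, 0.3), D = c(0.7, 0.3))
  ext2 <- extend_candidates(toy_candidates("A", 0.5), prof2)
  expect_equal(ext2$short_score[ext2$specialist_id == "D"], 1)

  # below threshold: nothing added
  ext3 <- extend_candidates(toy_candidates("A", 0.5),
                            rbind(A = c(1, 0), E = c(0.4, 0.6)),
                            min_sim = 0.8)
  expect_identical(ext3$specialist_id, "A")

  # empty candidate set passes through; missing profile errors with the id
  empty <- specrec:::new_candidate_set(tibble::tibble(
    specialist_id = character(), ini_score = numeric(),
    provenance = character(), short_score = numeric()))
  expect_equal(nrow(extend_candidates(empty, profiles)), 0)
  expect_error(extend_candidates(toy_candidates("Z", 0.5), profiles), "Z")
})

test_that("extension keeps the max ini x short assignment and a per-seed cap", {
  profiles <- rbind(A = c(0.9, 0.1), B = c(0.5, 0.5), X = c(0.89, 0.11))
  cands <- toy_candidates(ids = c("A", "B"), ini = c(0.9, 0.3))
  ext <- extend_candidates(cands, profiles, min_sim = 0.1)
  x <- ext[ext$specialist_id == "X", ]
  simA <- js_similarity(profiles["A", ], profiles["X", ])
  simB <- js_similarity(profiles["B", ], profiles["X", ])
  expect_equal(x$ini_score * x$short_score, max(0.9 * simA, 0.3 * simB))
  # cap: with per_seed_cap = 0 nothing can be added
  ext0 <- extend_candidates(cands, profiles, min_sim = 0.1,
                            per_seed_cap = 0L)
  expect_setequal(ext0$specialist_id, c("A", "B"))
  # members never removed nor down-scored
  expect_true(all(cands$specialist_id %in% ext$specialist_id))
  expect_true(all(ext$ini_score[match(cands$specialist_id,
                                      ext$specialist_id)] >=
                    cands$ini_score))
})

test_that("top_words ranks each topic's vocabulary by probability", {
  m <- fit_lda(disjoint_docs(), K = 2, iterations = 100, seed = 6)
  tw <- top_words(m, 5)
  expect_length(tw, 2)
  for (t in tw) {
    expect_length(t, 5)
    expect_false(is.unsorted(rev(t)))
  }
})
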