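ledger_from <- function(df, horizon = 12L) {
  # df: specialist_id, t, count -> expand to dated records
  ref <- as.Date("2020-12-15")
  rows <- df[rep(seq_len(nrow(df)), df$count), c("specialist_id", "t")]
  dates <- seq(ref, by = "-1 month", length.out = horizon + 1)[rows$t + 1]
  activity_ledger(data.frame(specialist_id = rows$specialist_id,
                             date = dates),
                  reference_date = ref, horizon = horizon)
}

test_that("activity follows the exponentially decayed share formula", {
  # sole specialist, all activity now: AC = 1
  l1 <- ledger_from(data.frame(specialist_id = "S1", t = 0, count = 3))
  expect_equal(activity_scores(l1)$ac, 1)
  # N_j(0) = 2 of N(0) = 4 -> 0.5
  l2 <- ledger_from(data.frame(specialist_id = c("S1", "S2"), t = 0,
                               count = c(2, 2)))
  a2 <- activity_scores(l2)
  expect_equal(a2$ac[a2$specialist_id == "S1"], 0.5)
  # same counts shifted to t = 1 -> 0.5 * exp(-1)
  l3 <- ledger_from(data.frame(specialist_id = c("S1", "S2"), t = 1,
                               count = c(2, 2)))
  a3 <- activity_scores(l3)
  expect_equal(a3$ac[a3$specialist_id == "S1"], 0.5 * exp(-1),
               tolerance = 1e-12)
})

test_that("shifting any count bundle one period back strictly lowers AC", {
  # AC normalizes by each period's total, so the decay comparison needs the
  # background volume to be the same in both periods: a background
  # specialist contributes m consultations at t0 and t0 + 1 alike, making
  # both totals c + m whichever period holds the bundle.
  set.seed(3)
  for (i in 1:20) {
    t0 <- sample(0:10, 1)
    m <- sample(1:4, 1)
    bundle <- sample(1:5, 1)
    base <- data.frame(specialist_id = c("S1", "S2", "S2"),
                       t = c(t0, t0, t0 + 1), count = c(bundle, m, m))
    shifted <- base
    shifted$t[1] <- t0 + 1
    ac0 <- activity_scores(ledger_from(base))
    ac1 <- activity_scores(ledger_from(shifted))
    expect_lt(ac1$ac[ac1$specialist_id == "S1"],
              ac0$ac[ac0$specialist_id == "S1"])
  }
})

test_that("normalized activity pins the most active specialist at 1", {
  l <- ledger_from(data.frame(specialist_id = c("S1", "S1", "S2"),
                              t = c(0, 1, 1), count = c(2, 2, 2)))
  a <- activity_scores(l)
  expect_equal(max(a$lac), 1)
  expect_equal(a$lac, a$ac / max(a$ac))
  l1 <- ledger_from(data.frame(specialist_id = "S9", t = 2, count = 1))
  expect_equal(activity_scores(l1)$lac, 1)
})

test_that("activity ledger buckets by whole calendar months within the horizon", {
  cons <- data.frame(specialist_id = c("S1", "S1", "S1"),
                     date = as.Date(c("2020-12-01", "2020-11-30",
                                      "2018-01-01")))
  l <- activity_ledger(cons, reference_date = as.Date("2020-12-31"),
                       horizon = 12)
  expect_equal(sum(attr(l, "totals")), 2)  # the 2018 record is outside
  expect_equal(unname(attr(l, "totals")[c("0", "1")]), c(1, 1))
})

test_that("professional score is the bounded three-way product", {
  expect_equal(professional_score(1, 1, 1), 1)
  expect_equal(professional_score(0.5, 0.4, 1.0), 0.2)
  expect_equal(professional_score(0.3, 0, 0.9), 0)
  expect_error(professional_score(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(professional_score(0.5, -0.1, 0.5), "\\[0, 1\\]")
})

test_that("preference weights map questionnaire categories per the conversion table", {
  w <- preference_weights("Extremely like", "Like")
  expect_equal(w$omega_p, 4 / 7)
  expect_equal(w$omega_q, 3 / 7)
  f <- preference_weights("Fair", "Fair")
  expect_equal(c(f$omega_p, f$omega_q), c(0.5, 0.5))
  dd <- preference_weights("Extremely dislike", "extremely DISLIKE")
  expect_equal(c(dd$omega_p, dd$omega_q), c(0.5, 0.5))  # 0/0 fallback
  expect_error(preference_weights("Meh", "Fair"), "valid")
  # constraint holds across the whole table
  cats <- c("Extremely like", "Like", "Fair", "Dislike", "Extremely dislike")
  for (a in cats) for (b in cats) {
    ww <- preference_weights(a, b)
    expect_equal(ww$omega_p + ww$omega_q, 1)
    expect_true(ww$omega_p >= 0 && ww$omega_p <= 1)
  }
})

test_that("QoS updates keep the running mean over the rating multiset", {
  s <- qos_state("S1", c(4, 4))
  expect_equal(update_qos(s, 4)$qos, 4)
  expect_equal(update_qos(qos_state("S1", c(5, 3)), 4)$qos, 4)
  expect_equal(update_qos(qos_state("S1"), 4)$qos, 4)  # m = 0
  expect_error(update_qos(s, 6), "scale")
  # permutation invariance of the rating history
  set.seed(8)
  for (i in 1:20) {
    r <- runif(sample(2:10, 1), 0, 5)
    s1 <- qos_state("S", numeric())
    for (x in r) s1 <- update_qos(s1, x)
    s2 <- qos_state("S", numeric())
    for (x in sample(r)) s2 <- update_qos(s2, x)
    expect_equal(s1$qos, s2$qos, tolerance = 1e-12)
  }
})

test_that("QoS normalization pins the best-rated specialist at 1", {
  q <- qos_scores(tibble::tibble(specialist_id = c("S1", "S2"),
                                 qos = c(4.5, 3.0)))
  expect_equal(q$qos_score, c(1, 3 / 4.5), tolerance = 1e-12)
  one <- qos_scores(tibble::tibble(specialist_id = "S1", qos = 2))
  expect_equal(one$qos_score, 1)
  expect_error(qos_scores(tibble::tibble(specialist_id = "S1", qos = 0)),
               "zero")
})

test_that("hybrid ranking fuses normalized components linearly", {
  cands <- toy_candidates(ids = c("A", "B"), ini = c(1, 0.5))
  act <- tibble::tibble(specialist_id = c("A", "B"), ac = c(1, 1),
                        lac = c(1, 1))
  qos <- tibble::tibble(specialist_id = c("A", "B"), qos = c(2, 4),
                        qos_score = c(0.5, 1))
  # prof' = (1, 0.5); omega_p = 0.6 -> compre (0.80, 0.70)
  r <- hybrid_rank(cands, act, qos, fixed_weights(0.6))
  expect_equal(r$compre_score, c(0.80, 0.70), tolerance = 1e-12)
  expect_identical(r$specialist_id, c("A", "B"))
  # degenerate weights reduce to single-component rankings
  rp <- hybrid_rank(cands, act, qos, fixed_weights(1))
  expect_identical(rp$specialist_id,
                   c("A", "B")[order(-c(1, 0.5))])
  rq <- hybrid_rank(cands, act, qos, fixed_weights(0))
  expect_identical(rq$specialist_id, c("B", "A"))
  expect_error(hybrid_rank(cands, act[1, ], qos, fixed_weights(0.5)), "B")
})

test_that("compre_score stays in [0, 1] and is monotone in omega_p", {
  set.seed(4)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    ids <- sprintf("S%d", 1:n)
    cands <- toy_candidates(ids = ids, ini = runif(n))
    act <- tibble::tibble(specialist_id = ids, ac = 1, lac = runif(n))
    act$lac[sample(n, 1)] <- 1
    qos <- tibble::tibble(specialist_id = ids, qos = 1,
                          qos_score = runif(n))
    qos$qos_score[sample(n, 1)] <- 1
    prev <- NULL
    for (wp in c(0, 0.3, 0.7, 1)) {
      r <- hybrid_rank(cands, act, qos, fixed_weights(wp), n = n)
      expect_true(all(r$compre_score >= 0 & r$compre_score <= 1))
      cur <- setNames(r$prof_score_norm - r$qos_score, r$specialist_id)
      sc <- setNames(r$compre_score, r$specialist_id)[ids]
      if (!is.null(prev)) {
        # pointwise: larger omega_p raises scores of prof-dominant items
        d <- sc - prev
        expect_true(all(d[cur[ids] > 0] >= -1e-12))
      }
      prev <- sc
    }
  }
})

test_that("equal QoS reduces the hybrid ranking to the professional one", {
  set.seed(6)
  ids <- sprintf("S%d", 1:5)
  cands <- toy_candidates(ids = ids, ini = runif(5))
  act <- tibble::tibble(specialist_id = ids, ac = 1, lac = c(runif(4), 1))
  qos <- tibble::tibble(specialist_id = ids, qos = 3, qos_score = 1)
  prof_rank <- hybrid_rank(cands, act, qos, fixed_weights(1))$specialist_id
  for (wp in c(0.2, 0.5, 0.8))
    expect_identical(hybrid_rank(cands, act, qos,
                                 fixed_weights(wp))$specialist_id,
                     prof_rank)
})
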