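#' Monthly activity ledger from consultation records
#'
#' Buckets consultations by whole-month age t relative to a reference month
#' (t = 0 is the current period); periods older than `horizon` are dropped.
#'
#' @param consultations data frame with `specialist_id` and `date`.
#' @param reference_date date anchoring t = 0 (default: latest consultation).
#' @param horizon maximum period age retained (default 12 months).
#' @param specialists ids to include even with zero counts (default: those in
#'   the log).
#' @return Object of class `specrec_ledger`: tibble of
#'   (`specialist_id`, `t`, `count`) plus attribute `totals` (named vector
#'   N(t)).
#' @export
activity_ledger <- function(consultations, reference_date = NULL,
                            horizon = 12L, specialists = NULL) {
  stopifnot(all(c("specialist_id", "date") %in% names(consultations)))
  d <- as.Date(consultations$date)
  if (is.null(reference_date)) reference_date <- max(d)
  reference_date <- as.Date(reference_date)
  ym <- function(x) as.integer(format(x, "%Y")) * 12L +
    as.integer(format(x, "%m"))
  t <- ym(reference_date) - ym(d)
  keep <- t >= 0 & t <= horizon
  df <- data.frame(specialist_id = consultations$specialist_id[keep],
                   t = t[keep])
  if (is.null(specialists)) specialists <- sort(unique(df$specialist_id))
  tab <- table(factor(df$specialist_id, levels = specialists),
               factor(df$t, levels = 0:horizon))
  ledger <- tibble::tibble(
    specialist_id = rep(specialists, times = horizon + 1L),
    t = rep(0:horizon, each = length(specialists)),
    count = as.integer(tab))
  ledger <- ledger[ledger$count > 0 | ledger$t == 0, ]
  totals <- vapply(0:horizon, function(tt)
    sum(ledger$count[ledger$t == tt]), numeric(1))
  structure(ledger, totals = stats::setNames(totals, 0:horizon),
            horizon = horizon, specialists = specialists,
            class = c("specrec_ledger", class(ledger)))
}

#' Time-decayed activity scores
#'
#' The raw activity of specialist j is
#' `AC_j = sum_t N_j(t) * exp(-t) / N(t)` -- the specialist's share of each
#' period's consultations, exponentially discounted by period age -- and the
#' normalized activity is `LAC_j = AC_j / AC_max`, so the most active
#' specialist scores 1.
#'
#' @param ledger a `specrec_ledger`.
#' @return tibble of (`specialist_id`, `ac`, `lac`).
#' @export
activity_scores <- function(ledger) {
  stopifnot(inherits(ledger, "specrec_ledger"))
  if (any(ledger$count < 0)) stop("negative consultation counts")
  totals <- attr(ledger, "totals")
  specialists <- attr(ledger, "specialists")
  N <- totals[as.character(ledger$t)]
  contrib <- ifelse(N > 0, ledger$count * exp(-ledger$t) / N, 0)
  ac <- vapply(specialists, function(s)
    sum(contrib[ledger$specialist_id == s]), numeric(1))
  if (all(ac == 0)) stop("no activity signal: all AC are zero")
  tibble::tibble(specialist_id = specialists, ac = unname(ac),
                 lac = unname(ac / max(ac)))
}

#' Professional recommendation index
#'
#' `prof_score = LAC * ini_score * short_score`; the product of normalized
#' activity, the initial (EMR-similarity) recommendation index, and the
#' topic-space recommendation index. Vectorized.
#'
#' @param lac,ini_score,short_score values in \[0, 1\].
#' @return prof_score in \[0, 1\].
#' @export
professional_score <- function(lac, ini_score, short_score) {
  x <- c(lac, ini_score, short_score)
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop("professional_score inputs must lie in [0, 1]")
  lac * ini_score * short_score
}

#' Subjective preference weights from questionnaire categories
#'
#' Maps the Likert-style answers Extremely like / Like / Fair / Dislike /
#' Extremely dislike to 4 / 3 / 2 / 1 / 0 and converts the pair of answers
#' (professional recommendation, service quality) into normalized weights
#' `omega_p = a / (a + b)`, `omega_q = b / (a + b)`. Both answers "Extremely
#' dislike" (0/0) fall back to equal weights so the constraint
#' `omega_p + omega_q = 1` always holds.
#'
#' @param prof_choice,qos_choice preference category strings (case- and
#'   space-insensitive).
#' @return Object of class `specrec_weights`: list `(omega_p, omega_q)`.
#' @export
preference_weights <- function(prof_choice, qos_choice) {
  levels <- c("extremely like" = 4, "like" = 3, "fair" = 2, "dislike" = 1,
              "extremely dislike" = 0)
  lookup <- function(x) {
    key <- tolower(trimws(gsub("\\s+", " ", x)))
    if (!key %in% names(levels))
      stop("unknown preference category '", x, "'; valid: ",
           paste(names(levels), collapse = ", "))
    levels[[key]]
  }
  a <- lookup(prof_choice)
  b <- lookup(qos_choice)
  if (a + b == 0) {
    w <- c(0.5, 0.5)
  } else {
    w <- c(a, b) / (a + b)
  }
  structure(list(omega_p = w[1], omega_q = w[2]), class = "specrec_weights")
}

#' Fixed preference weights
#'
#' Constructs a `specrec_weights` pair directly, e.g. for sweeps over
#' `omega_q`.
#'
#' @param omega_p professional-recommendation weight in \[0, 1\];
#'   `omega_q = 1 - omega_p`.
#' @return A `specrec_weights` object.
#' @export
fixed_weights <- function(omega_p) {
  if (is.na(omega_p) || omega_p < 0 || omega_p > 1)
    stop("omega_p must lie in [0, 1]")
  structure(list(omega_p = omega_p, omega_q = 1 - omega_p),
            class = "specrec_weights")
}

#' Update a specialist's objective QoS state with a new rating
#'
#' Appends the post-service rating and recomputes the running mean
#' evaluation value; order of arrival never matters beyond the multiset of
#' ratings.
#'
#' @param state list with `specialist_id` and numeric `ratings` (possibly
#'   empty), as produced by `qos_state()`.
#' @param new_rating rating on the configured scale.
#' @param scale two-element numeric bounds (default 0-5).
#' @return the updated state with `qos` = mean of all ratings.
#' @export
update_qos <- function(state, new_rating, scale = c(0, 5)) {
  if (is.na(new_rating) || new_rating < scale[1] || new_rating > scale[2])
    stop("rating outside the configured scale [", scale[1], ", ", scale[2],
         "]")
  state$ratings <- c(state$ratings, new_rating)
  state$qos <- mean(state$ratings)
  state
}

#' @rdname update_qos
#' @param specialist_id id for a fresh QoS state.
#' @param ratings initial ratings (e.g. a seeded hot-ranking value).
#' @export
qos_state <- function(specialist_id, ratings = numeric()) {
  list(specialist_id = specialist_id, ratings = ratings,
       qos = if (length(ratings)) mean(ratings) else NA_real_)
}

#' Normalized objective QoS scores
#'
#' `qos_score_j = qos_j / qos_max`; the best-rated specialist scores 1.
#'
#' @param qos tibble/data frame with `specialist_id` and mean `qos` columns.
#' @return the input with a `qos_score` column added.
#' @export
qos_scores <- function(qos) {
  stopifnot(all(c("specialist_id", "qos") %in% names(qos)))
  if (any(is.na(qos$qos) | qos$qos < 0)) stop("qos values must be >= 0")
  m <- max(qos$qos)
  if (m == 0) stop("all QoS values are zero: no feedback signal")
  qos$qos_score <- qos$qos / m
  tibble::as_tibble(qos)
}

#' Fused hybrid ranking
#'
#' Computes `prof_score = LAC * ini_score * short_score` per candidate,
#' normalizes it by the maximum over the candidate pool, and fuses it with
#' the normalized objective QoS score:
#' `compre_score = omega_p * prof_score' + omega_q * qos_score`.
#' Returns the top `n` with the full component breakdown so every ranking is
#' auditable. Candidates without a `short_score` (no topic-extension stage
#' run) count as members with `short_score = 1`; a negative `ini_score`
#' (possible for an anti-similar EMR cosine) carries no recommendation
#' strength and is clipped to 0 before the product.
#'
#' @param candidates a `specrec_candidates` set.
#' @param activity tibble from [activity_scores()] covering the candidates.
#' @param qos tibble from [qos_scores()] covering the candidates.
#' @param weights a `specrec_weights` pair.
#' @param n list size (default 10).
#' @return Object of class `specrec_recommendation`: tibble sorted by
#'   `compre_score` descending (ties by specialist id) with columns
#'   `specialist_id`, `ini_score`, `short_score`, `lac`, `prof_score`,
#'   `prof_score_norm`, `qos_score`, `compre_score`.
#' @export
hybrid_rank <- function(candidates, activity, qos, weights, n = 10L) {
  stopifnot(inherits(candidates, "specrec_candidates"),
            inherits(weights, "specrec_weights"))
  if (nrow(candidates) == 0) stop("empty candidate set")
  ids <- candidates$specialist_id
  ai <- match(ids, activity$specialist_id)
  qi <- match(ids, qos$specialist_id)
  if (anyNA(ai))
    stop("no activity score for: ", paste(ids[is.na(ai)], collapse = ", "))
  if (anyNA(qi))
    stop("no QoS score for: ", paste(ids[is.na(qi)], collapse = ", "))

  short <- ifelse(is.na(candidates$short_score), 1, candidates$short_score)
  ini <- pmin(pmax(candidates$ini_score, 0), 1)
  lac <- activity$lac[ai]
  prof <- professional_score(lac, ini, short)
  prof_norm <- if (max(prof) > 0) prof / max(prof) else prof
  qsc <- qos$qos_score[qi]
  compre <- weights$omega_p * prof_norm + weights$omega_q * qsc

  out <- tibble::tibble(specialist_id = ids,
                        provenance = candidates$provenance,
                        ini_score = candidates$ini_score,
                        short_score = short, lac = lac,
                        prof_score = prof, prof_score_norm = prof_norm,
                        qos_score = qsc, compre_score = compre)
  out <- out[order(-out$compre_score, out$specialist_id), ]
  out <- utils::head(out, min(n, nrow(out)))
  structure(out, class = c("specrec_recommendation", class(out)))
}
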