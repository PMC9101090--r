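#' Per-item correctness of a recommendation list
#'
#' A recommended specialist is correct when their profile's disease-label set
#' intersects the target patient's disease labels. Labels are assumed to be
#' normalized with the same synonym map as the corpus.
#'
#' @param recommended character vector of specialist ids, in rank order.
#' @param target_labels character vector of the target patient's disease
#'   labels (empty set makes every item incorrect).
#' @param profiles named list mapping specialist id -> character vector of
#'   disease labels.
#' @return logical vector, one flag per recommended item.
#' @export
correctness <- function(recommended, target_labels, profiles) {
  missing <- setdiff(recommended, names(profiles))
  if (length(missing))
    stop("specialist(s) without profile: ", paste(missing, collapse = ", "))
  vapply(recommended, function(s)
    length(intersect(target_labels, profiles[[s]])) > 0, logical(1),
    USE.NAMES = FALSE)
}

#' Precision and recall at N
#'
#' `Pre@N = TP / (TP + FP)` and `Rec@N = TP / (TP + FN)` with `TP` the number
#' of correct items in the list, `FP = N - TP`, and
#' `FN = total_relevant - TP`.
#'
#' @param correct_flags logical vector of per-item correctness (length N).
#' @param total_relevant number of relevant specialists in the retrieval
#'   universe (on synthetic data: the size of the ground-truth best-match
#'   list).
#' @return list with `n`, `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
precision_recall_at_n <- function(correct_flags, total_relevant) {
  tp <- sum(correct_flags)
  n <- length(correct_flags)
  if (total_relevant < tp)
    stop("total_relevant (", total_relevant, ") smaller than the number of ",
         "correct items (", tp, ")")
  fp <- n - tp
  fn <- total_relevant - tp
  list(n = n, tp = tp, fp = fp, fn = fn,
       precision = if (n > 0) tp / n else NA_real_,
       recall = if (total_relevant > 0) tp / total_relevant else NA_real_)
}

#' Mean relevance of a recommendation list
#'
#' Mean cosine similarity between the target patient's EMR vector and each
#' recommended specialist's aggregate document vector, both in the same
#' embedding space.
#'
#' @param spec_vectors matrix of specialist vectors (one row per recommended
#'   specialist).
#' @param target numeric target EMR vector of matching dimension.
#' @return mean cosine similarity.
#' @export
relevance <- function(spec_vectors, target) {
  spec_vectors <- rbind(spec_vectors)
  if (ncol(spec_vectors) != length(target))
    stop("dimension mismatch between specialist vectors and target")
  mean(apply(spec_vectors, 1, cosine_similarity, b = target))
}

#' Rank-weighted rationality scores of a recommendation list
#'
#' Each rank r (0-based) gets a priority `prior_r = (L - r) / sum(0:(L-1))`
#' (for a 10-item list, `(10 - r) / 45`), and the rationality score is the
#' priority times the mean questionnaire rating at that rank:
#' `score_r = prior_r * mean(ratings_r)`. The denominator `sum(0:(L-1))`
#' follows the printed rule even though the priorities then do not sum to 1;
#' `normalized = TRUE` switches to the variant dividing by `sum(L - r)` so
#' that they do.
#'
#' @param rank_ratings list of numeric rating vectors (1-5), one per rank,
#'   best rank first.
#' @param list_size expected list size (default 10).
#' @param normalized use the normalizing denominator instead of the printed
#'   one.
#' @return tibble with `rank`, `prior`, `mean_rating`, `score`.
#' @export
rationality <- function(rank_ratings, list_size = 10L, normalized = FALSE) {
  if (length(rank_ratings) != list_size)
    stop("expected ", list_size, " rating vectors, got ",
         length(rank_ratings))
  all_r <- unlist(rank_ratings)
  if (any(all_r < 1 | all_r > 5))
    stop("ratings must lie in 1..5")
  r <- seq_len(list_size) - 1L
  den <- if (normalized) sum(list_size - r) else sum(r)
  prior <- (list_size - r) / den
  mr <- vapply(rank_ratings, mean, numeric(1))
  tibble::tibble(rank = r, prior = prior, mean_rating = mr,
                 score = prior * mr)
}
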