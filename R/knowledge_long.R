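#' Specialist knowledge-attribute matrix
#'
#' Binary specialist x attribute expertise matrix (`a[j, p] = 1` when
#' specialist j is specialized in attribute/disease p), with `NA` marking
#' missing profile cells and per-attribute weights.
#'
#' @param values integer/numeric matrix of 0/1 with `NA` for missing; rownames
#'   are specialist ids, colnames attribute ids.
#' @param weights nonnegative per-attribute weights (default uniform).
#' @return Object of class `specrec_knowledge`.
#' @export
knowledge_matrix <- function(values, weights = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("knowledge matrix needs specialist rownames and attribute colnames")
  obs <- values[!is.na(values)]
  if (length(obs) && !all(obs %in% c(0, 1)))
    stop("observed knowledge cells must be 0 or 1")
  if (is.null(weights)) weights <- rep(1, ncol(values))
  if (length(weights) != ncol(values) || any(weights < 0))
    stop("weights must be nonnegative, one per attribute")
  if (sum(weights) <= 0) stop("attribute weights must sum to > 0")
  structure(list(values = values, weights = as.numeric(weights)),
            class = "specrec_knowledge")
}

#' Read a knowledge matrix from CSV
#'
#' Header `specialist_id,attr_1,...`; cells `0`, `1` or empty (missing).
#'
#' @param path CSV file path.
#' @param weights optional per-attribute weights.
#' @return A `specrec_knowledge` object.
#' @export
read_knowledge_matrix <- function(path, weights = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  stopifnot(names(df)[1] == "specialist_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df$specialist_id
  knowledge_matrix(m, weights)
}

#' Impute missing knowledge-matrix cells by column frequency
#'
#' A missing cell `a[j, p]` is set to 1 when the fraction of *observed* ones
#' in attribute column p is at least 0.5, otherwise 0. Counting unobserved
#' cells as zeros would bias filling toward 0, so the fraction is taken over
#' observed entries only; a column with no observed value imputes to 0 (no
#' evidence of expertise). Column-local, hence row-permutation equivariant.
#'
#' @param km a `specrec_knowledge` matrix, possibly with `NA` cells.
#' @return A `specrec_knowledge` matrix with no missing cells.
#' @export
impute_matrix <- function(km) {
  stopifnot(inherits(km, "specrec_knowledge"))
  v <- km$values
  for (p in seq_len(ncol(v))) {
    col <- v[, p]
    if (anyNA(col)) {
      frac <- mean(col == 1, na.rm = TRUE)
      fill <- if (!is.nan(frac) && frac >= 0.5) 1 else 0
      v[is.na(col), p] <- fill
    }
  }
  knowledge_matrix(v, km$weights)
}

#' Weighted Jaccard similarity between two binary attribute rows
#'
#' `sum(w * pmin(x, y)) / sum(w * pmax(x, y))`; with uniform weights this is
#' the plain Jaccard coefficient. Two all-zero rows have similarity 0 by
#' convention.
#'
#' @param x,y binary vectors of equal length (no `NA`; impute first).
#' @param weights nonnegative weights, recycled to uniform when omitted.
#' @return similarity in \[0, 1\].
#' @export
weighted_jaccard <- function(x, y, weights = rep(1, length(x))) {
  if (length(x) != length(y)) stop("rows differ in length")
  if (anyNA(x) || anyNA(y)) stop("rows contain missing values; impute first")
  if (any(weights < 0)) stop("weights must be nonnegative")
  den <- sum(weights * pmax(x, y))
  if (den == 0) return(0)
  sum(weights * pmin(x, y)) / den
}

#' Rarity-based attribute weights
#'
#' `w_p = ln(n / (1 + sum_j a[j, p]))` truncated at 0: rare expertise
#' attributes count more than ubiquitous ones. Offered as an alternative to
#' the uniform default.
#'
#' @param km an imputed `specrec_knowledge` matrix.
#' @return numeric weight vector, one per attribute.
#' @export
rarity_weights <- function(km) {
  stopifnot(inherits(km, "specrec_knowledge"), !anyNA(km$values))
  pmax(log(nrow(km$values) / (1 + colSums(km$values))), 0)
}

#' Identify newly registered specialists from the consultation log
#'
#' Specialists with fewer than `max_consultations` consultations (default:
#' fewer than three) are treated as newly registered for cold-start repair.
#'
#' @param consultations consultation-record data frame.
#' @param specialists ids to classify (defaults to those in the log plus any
#'   extra passed here); ids absent from the log have zero consultations.
#' @param max_consultations threshold; "fewer than this" is newly registered.
#' @return character vector of newly registered specialist ids.
#' @export
newly_registered <- function(consultations, specialists = NULL,
                             max_consultations = 3L) {
  counts <- table(consultations$specialist_id)
  if (is.null(specialists))
    specialists <- names(counts)
  n <- as.integer(counts[specialists])
  n[is.na(n)] <- 0L
  sort(specialists[n < max_consultations])
}

#' Cold-start repair of the candidate set
#'
#' For each newly registered specialist j, members h of the candidate set
#' with long-term knowledge similarity `SimKnowledge(j, h) >= threshold` are
#' collected; when q >= 1 of them qualify, the specialist's recommendation
#' index is updated to
#' `ini_score'_j = ini_score_j + (1/q) * sum_h ini_score_h * SimKnowledge(j, h)`
#' and j is inserted with provenance `"cold-start"` (its prior `ini_score` is
#' 0 when it was absent from the set). Existing members are never removed or
#' down-scored; the set is re-sorted by `ini_score`.
#'
#' @param candidates a `specrec_candidates` set.
#' @param km an *imputed* `specrec_knowledge` matrix covering the candidates
#'   and the newly registered specialists.
#' @param newly character vector of newly registered specialist ids.
#' @param threshold similarity cut-off (default 0.7).
#' @return The updated `specrec_candidates` set.
#' @export
update_cold_start <- function(candidates, km, newly, threshold = 0.7) {
  stopifnot(inherits(candidates, "specrec_candidates"),
            inherits(km, "specrec_knowledge"))
  if (anyNA(km$values)) stop("knowledge matrix has missing cells; impute first")
  if (!length(newly)) return(candidates)
  absent <- setdiff(newly, rownames(km$values))
  if (length(absent))
    stop("newly registered specialist(s) absent from knowledge matrix: ",
         paste(absent, collapse = ", "))
  members <- candidates$specialist_id
  absent_m <- setdiff(members, rownames(km$values))
  if (length(absent_m))
    stop("candidate specialist(s) absent from knowledge matrix: ",
         paste(absent_m, collapse = ", "))

  out <- candidates
  for (j in sort(newly)) {
    sims <- vapply(members, function(h)
      weighted_jaccard(km$values[j, ], km$values[h, ], km$weights),
      numeric(1))
    keep <- members != j & sims >= threshold
    q <- sum(keep)
    if (q == 0) next
    boost <- mean(candidates$ini_score[match(members[keep], members)] *
                    sims[keep])
    if (j %in% out$specialist_id) {
      i <- match(j, out$specialist_id)
      out$ini_score[i] <- out$ini_score[i] + boost
      out$provenance[i] <- "cold-start"
    } else {
      out <- tibble::add_row(out, specialist_id = j, ini_score = boost,
                             provenance = "cold-start",
                             short_score = NA_real_)
    }
  }
  new_candidate_set(sort_candidates(out))
}
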