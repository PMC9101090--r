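#' Configuration of the synthetic telemedicine world
#'
#' The generator emulates the shape of a telemedicine consultation log plus
#' an online profile registry: topic-structured EMR token documents,
#' per-specialist expertise mixtures, a binary knowledge matrix with
#' missingness, heterogeneous monthly consultation volumes over a year, and
#' bounded service-quality ratings. Tokens are synthetic symbols
#' (`w0001`, ...), so no language-specific segmentation is involved.
#'
#' @param n_specialists number of specialists (default 50).
#' @param n_patients number of patient consultations (default 1000).
#' @param n_topics number of planted topics K* (default 5).
#' @param vocab_size vocabulary size V (default 300).
#' @param doc_length mean EMR length in tokens (Poisson, min 3; default 20).
#' @param missing_rate fraction of knowledge cells masked as missing
#'   (default 0.1).
#' @param months number of monthly periods, t = 0..months (default 12).
#' @param rating_noise standard deviation of the rating noise around each
#'   specialist's latent quality (default 0.5; quality is independent of
#'   topic relevance so preference-weight sweeps are meaningful).
#' @param topic_concentration Dirichlet concentration of specialist topic
#'   mixtures (default 0.3: most mass on 1-2 topics).
#' @param attr_threshold mixture mass above which a specialist is considered
#'   specialized in a topic's disease attribute (default 0.2, giving 1-3
#'   expertise attributes per specialist on average).
#' @param planted_newcomer plant one newly registered specialist (a single
#'   consultation) whose knowledge row duplicates the strongest veteran on
#'   the target topic, for cold-start validation.
#' @param synonym_rate probability that an occurrence of a synonym-mapped
#'   word is written in its variant form.
#' @param stopword_rate expected number of stop-word tokens injected per
#'   document.
#' @param end_date date of the most recent period (t = 0).
#' @param seed integer RNG seed.
#' @return Object of class `specrec_world_config`.
#' @export
world_config <- function(n_specialists = 50L, n_patients = 1000L,
                         n_topics = 5L, vocab_size = 300L, doc_length = 20,
                         missing_rate = 0.1, months = 12L,
                         rating_noise = 0.5, topic_concentration = 0.3,
                         attr_threshold = 0.2, planted_newcomer = TRUE,
                         synonym_rate = 0.3, stopword_rate = 1,
                         end_date = as.Date("2020-12-31"), seed = 1L) {
  cfg <- list(n_specialists = as.integer(n_specialists),
              n_patients = as.integer(n_patients),
              n_topics = as.integer(n_topics),
              vocab_size = as.integer(vocab_size),
              doc_length = doc_length, missing_rate = missing_rate,
              months = as.integer(months), rating_noise = rating_noise,
              topic_concentration = topic_concentration,
              attr_threshold = attr_threshold,
              planted_newcomer = isTRUE(planted_newcomer),
              synonym_rate = synonym_rate, stopword_rate = stopword_rate,
              end_date = as.Date(end_date), seed = as.integer(seed))
  if (any(unlist(cfg[c("n_specialists", "n_patients", "n_topics",
                       "vocab_size", "months")]) <= 0))
    stop("all counts must be positive")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (cfg$vocab_size < cfg$n_topics)
    stop("vocab_size must be at least n_topics")
  structure(cfg, class = "specrec_world_config")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic world with known ground truth
#'
#' Samples topic-word distributions phi* (each topic concentrated on its own
#' vocabulary block), sparse specialist topic mixtures, consultation EMRs
#' drawn token-by-token via topic-then-word draws, a knowledge matrix from
#' the mixture-threshold rule with cells masked at `missing_rate`,
#' heterogeneous monthly consultation counts, and noisy bounded ratings from
#' a latent quality that is independent of topic relevance. A designated
#' target patient is drawn from one topic, and the ground-truth best-match
#' specialists (those whose mixture mass on that topic passes
#' `attr_threshold`) are recorded. Fully reproducible from the config seed.
#'
#' @param config a `specrec_world_config`.
#' @return Object of class `specrec_world`; see fields in the source. The
#'   `truth` element is never consumed by the recommendation pipeline.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "specrec_world_config"))
  set.seed(config$seed)
  K <- config$n_topics
  V <- config$vocab_size
  nS <- config$n_specialists
  vocab <- sprintf("w%04d", seq_len(V))
  spec_ids <- sprintf("S%03d", seq_len(nS))

  # topic-word distributions: block-diagonal-ish, distinct topics
  block <- split(seq_len(V), cut(seq_len(V), K, labels = FALSE))
  phi <- matrix(0, K, V, dimnames = list(sprintf("topic_%d", 1:K), vocab))
  for (k in seq_len(K)) {
    shape <- rep(0.05, V)
    shape[block[[k]]] <- 2
    g <- stats::rgamma(V, shape = shape)
    phi[k, ] <- g / sum(g)
  }

  mixtures <- .rdirichlet(nS, rep(config$topic_concentration, K))
  rownames(mixtures) <- spec_ids
  colnames(mixtures) <- rownames(phi)

  # target topic: prefer a topic several specialists are specialized in
  n_dominant <- colSums(mixtures >= config$attr_threshold)
  eligible <- which(n_dominant >= 2)
  if (!length(eligible)) eligible <- which.max(n_dominant)
  k_star <- if (length(eligible) == 1) eligible else sample(eligible, 1)

  newcomer <- anchor <- NA_character_
  veterans <- spec_ids
  if (config$planted_newcomer && nS >= 2) {
    newcomer <- spec_ids[nS]
    veterans <- spec_ids[-nS]
    anchor <- veterans[which.max(mixtures[veterans, k_star])]
    mixtures[newcomer, ] <- mixtures[anchor, ]
  }

  # consultation volume: heterogeneous rates over veterans; newcomer gets
  # exactly one consultation (fewer than three => newly registered)
  rate <- stats::setNames(stats::rlnorm(length(veterans), 0, 1), veterans)
  assigned <- sample(veterans, config$n_patients, replace = TRUE,
                     prob = rate)
  if (!is.na(newcomer)) assigned <- c(assigned, newcomer)
  n_cons <- length(assigned)
  patient_ids <- sprintf("p%05d", seq_len(n_cons))

  # month age: recency-skewed so N(t) varies across periods
  t_age <- sample(0:(config$months - 1L), n_cons, replace = TRUE,
                  prob = exp(-0.1 * (0:(config$months - 1L))))
  ref_m <- as.integer(format(config$end_date, "%Y")) * 12L +
    as.integer(format(config$end_date, "%m"))
  m_idx <- ref_m - t_age
  dates <- as.Date(sprintf("%04d-%02d-%02d", (m_idx - 1L) %/% 12L,
                           (m_idx - 1L) %% 12L + 1L,
                           sample(1:28, n_cons, replace = TRUE)))

  # synonym and stop-word dictionaries exercised by the preprocessing stage
  syn_words <- vocab[seq_len(min(10L, V))]
  synonyms <- stats::setNames(syn_words, paste0("syn_", syn_words))
  stop_tokens <- c("stop_the", "stop_of", "stop_and")
  dicts <- dictionaries(stopwords = stop_tokens, synonyms = synonyms,
                        user_terms = character())

  draw_doc <- function(mix) {
    len <- max(3L, stats::rpois(1, config$doc_length))
    z <- sample.int(K, len, replace = TRUE, prob = mix)
    w <- character(len)
    for (k in unique(z)) {
      idx <- which(z == k)
      w[idx] <- vocab[sample.int(V, length(idx), replace = TRUE,
                                 prob = phi[k, ])]
    }
    # write some synonym-mapped words in their variant form
    is_syn <- w %in% syn_words & stats::runif(len) < config$synonym_rate
    w[is_syn] <- paste0("syn_", w[is_syn])
    n_stop <- stats::rpois(1, config$stopword_rate)
    if (n_stop > 0) {
      pos <- sample(length(w) + 1, min(n_stop, 3), replace = TRUE)
      w <- append(w, sample(stop_tokens, min(n_stop, 3), replace = TRUE),
                  after = pos[1] - 1)
    }
    list(tokens = w, topics = z)
  }

  texts <- character(n_cons)
  for (i in seq_len(n_cons))
    texts[i] <- paste(draw_doc(mixtures[assigned[i], ])$tokens,
                      collapse = " ")
  consultations <- tibble::tibble(
    patient_id = patient_ids, specialist_id = assigned,
    department = "IMD", date = dates, text = texts)

  # knowledge matrix: attribute p <-> specialization in topic p
  attr_names <- sprintf("disease_%d", seq_len(K))
  A <- matrix(as.integer(mixtures >= config$attr_threshold), nS, K,
              dimnames = list(spec_ids, attr_names))
  A_true <- A
  mask <- matrix(stats::runif(nS * K) < config$missing_rate, nS, K)
  if (!is.na(newcomer)) mask[match(c(newcomer, anchor), spec_ids), ] <- FALSE
  A[mask] <- NA_integer_

  # latent quality independent of topics; ratings clipped to the 0-5 scale
  quality <- stats::runif(nS, 2.5, 5)
  ratings <- round(pmin(5, pmax(0, quality +
                                  stats::rnorm(nS, 0, config$rating_noise))),
                   2)
  labels <- apply(A_true == 1, 1, function(r) attr_names[r],
                  simplify = FALSE)
  profiles <- tibble::tibble(
    specialist_id = spec_ids,
    labels = unname(labels),
    qos = ratings,
    n_consultations = as.integer(table(factor(assigned,
                                              levels = spec_ids))))

  target_mix <- rep(0.1 / (K - 1), K)
  target_mix[k_star] <- 0.9
  target_tokens <- draw_doc(target_mix)$tokens
  best_match <- spec_ids[A_true[, k_star] == 1]

  structure(list(
    config = config, vocabulary = vocab, phi_star = phi,
    mixtures = mixtures, consultations = consultations,
    knowledge = knowledge_matrix(A),
    knowledge_true = knowledge_matrix(A_true),
    profiles = profiles, dicts = dicts,
    target = list(patient_id = "p_target",
                  text = paste(target_tokens, collapse = " "),
                  topic = unname(k_star),
                  labels = attr_names[k_star]),
    truth = list(target_topic = unname(k_star),
                 target_labels = attr_names[k_star],
                 best_match = best_match,
                 newcomer = newcomer, anchor = anchor,
                 quality = stats::setNames(quality, spec_ids))),
    class = "specrec_world")
}

#' @export
print.specrec_world <- function(x, ...) {
  cat("<specrec_world> ", x$config$n_specialists, " specialists, ",
      nrow(x$consultations), " consultations, K* = ", x$config$n_topics,
      ", V = ", x$config$vocab_size, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic world as pipeline input files
#'
#' Emits exactly the external interface the pipeline consumes --
#' `consultations.csv`, `profiles.json`, `knowledge.csv`, `stopwords.txt`,
#' `synonyms.tsv`, `user_terms.txt`, `target_emr.txt` -- plus `truth.json`,
#' which the pipeline never reads.
#'
#' @param world a `specrec_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_fixture <- function(world, dir) {
  stopifnot(inherits(world, "specrec_world"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  p <- function(f) file.path(dir, f)

  cons <- world$consultations
  cons$date <- format(cons$date, "%Y-%m-%d")
  utils::write.csv(cons, p("consultations.csv"), row.names = FALSE)

  jsonlite::write_json(world$profiles, p("profiles.json"), dataframe = "rows",
                       auto_unbox = FALSE, digits = NA)

  km <- world$knowledge$values
  kdf <- data.frame(specialist_id = rownames(km), km, check.names = FALSE)
  utils::write.csv(kdf, p("knowledge.csv"), row.names = FALSE, na = "")

  writeLines(world$dicts$stopwords, p("stopwords.txt"))
  writeLines(paste(names(world$dicts$synonyms), world$dicts$synonyms,
                   sep = "\t"), p("synonyms.tsv"))
  writeLines(world$dicts$user_terms, p("user_terms.txt"))
  writeLines(world$target$text, p("target_emr.txt"))

  jsonlite::write_json(world$truth[c("target_topic", "target_labels",
                                     "best_match", "newcomer", "anchor")],
                       p("truth.json"), auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(vapply(c("consultations.csv", "profiles.json", "knowledge.csv",
                     "stopwords.txt", "synonyms.tsv", "user_terms.txt",
                     "target_emr.txt", "truth.json"), p, character(1)))
}

#' Load a fixture directory written by [write_fixture()]
#'
#' @param dir directory containing the pipeline input files.
#' @return list with `consultations`, `profiles`, `knowledge`, `dicts`,
#'   `target_text`.
#' @export
load_workspace <- function(dir) {
  prof <- jsonlite::read_json(file.path(dir, "profiles.json"),
                              simplifyVector = TRUE, simplifyDataFrame = TRUE)
  prof <- tibble::as_tibble(prof)
  prof$labels <- lapply(prof$labels, unlist)
  list(consultations = read_consultations(file.path(dir,
                                                    "consultations.csv")),
       profiles = prof,
       knowledge = read_knowledge_matrix(file.path(dir, "knowledge.csv")),
       dicts = read_dictionaries(file.path(dir, "stopwords.txt"),
                                 file.path(dir, "synonyms.tsv"),
                                 file.path(dir, "user_terms.txt")),
       target_text = paste(readLines(file.path(dir, "target_emr.txt"),
                                     warn = FALSE), collapse = " "))
}
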