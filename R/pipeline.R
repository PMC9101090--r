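#' Pipeline configuration
#'
#' All tunables of the four-stage recommendation pipeline with their
#' defaults: candidate-set size 10, long-term knowledge similarity threshold
#' 0.7, topic-extension similarity threshold 0.8 (cap 10 per seed), LDA with
#' 500 Gibbs iterations, skip-gram embeddings of dimension 100 with window 5.
#'
#' @param n_candidates initial candidate-set and final list size.
#' @param sim_knowledge_threshold cold-start similarity threshold.
#' @param extension_min_sim,extension_cap topic-extension threshold and
#'   per-seed cap.
#' @param lda_k topic count used when `k_grid` is `NULL`.
#' @param k_grid optional grid for perplexity-based selection of the topic
#'   count; overrides `lda_k` when given.
#' @param lda_alpha,lda_beta,lda_iterations LDA hyperparameters
#'   (`lda_alpha = NULL` means `50 / K`).
#' @param embedding_dim,embedding_window,embedding_epochs,embedding_negative
#'   skip-gram parameters.
#' @param activity_horizon months of history entering the activity score.
#' @param qos_scale bounds of the rating scale.
#' @param newcomer_max_consultations specialists with fewer consultations
#'   than this are newly registered (default 3).
#' @param knowledge_weights `"uniform"` or `"rarity"` attribute weighting.
#' @param seed master seed for embeddings and LDA.
#' @return Object of class `specrec_config` (a list).
#' @export
pipeline_config <- function(n_candidates = 10L,
                            sim_knowledge_threshold = 0.7,
                            extension_min_sim = 0.8, extension_cap = 10L,
                            lda_k = 10L, k_grid = NULL, lda_alpha = NULL,
                            lda_beta = 0.01, lda_iterations = 500L,
                            embedding_dim = 100L, embedding_window = 5L,
                            embedding_epochs = 30L, embedding_negative = 5L,
                            activity_horizon = 12L, qos_scale = c(0, 5),
                            newcomer_max_consultations = 3L,
                            knowledge_weights = c("uniform", "rarity"),
                            seed = 1L) {
  structure(list(n_candidates = as.integer(n_candidates),
                 sim_knowledge_threshold = sim_knowledge_threshold,
                 extension_min_sim = extension_min_sim,
                 extension_cap = as.integer(extension_cap),
                 lda_k = as.integer(lda_k), k_grid = k_grid,
                 lda_alpha = lda_alpha, lda_beta = lda_beta,
                 lda_iterations = as.integer(lda_iterations),
                 embedding_dim = as.integer(embedding_dim),
                 embedding_window = as.integer(embedding_window),
                 embedding_epochs = as.integer(embedding_epochs),
                 embedding_negative = as.integer(embedding_negative),
                 activity_horizon = as.integer(activity_horizon),
                 qos_scale = qos_scale,
                 newcomer_max_consultations =
                   as.integer(newcomer_max_consultations),
                 knowledge_weights = match.arg(knowledge_weights),
                 seed = as.integer(seed)),
            class = "specrec_config")
}

#' Run the four-stage recommendation pipeline
#'
#' Executes preprocessing, patient feature modeling (initial candidate set),
#' long-term knowledge cold-start repair, short-term topic-space extension,
#' and the fused activity/QoS ranking. The stage log records the candidate
#' set after each stage, so the evolution of every recommendation is
#' auditable. Deterministic for fixed seeds.
#'
#' @param consultations consultation records (data frame or CSV path).
#' @param profiles specialist profiles: tibble with `specialist_id`, `labels`
#'   (list column) and `qos` (initial objective QoS, e.g. a hot-ranking
#'   score).
#' @param knowledge a `specrec_knowledge` matrix (may contain missing cells;
#'   imputed here).
#' @param dicts a `specrec_dictionaries` object.
#' @param target_text the target patient's EMR free text.
#' @param weights a `specrec_weights` object, or a length-2 character vector
#'   of questionnaire categories `(professional, service quality)`.
#' @param config a `specrec_config`.
#' @param stages_only return after the extension stage, without fusing; the
#'   returned object then carries everything needed to call [hybrid_rank()]
#'   repeatedly (e.g. for preference-weight sweeps) without refitting.
#' @return Object of class `specrec_run`: list with `recommendation`,
#'   `stages` (named list of candidate sets: initial, cold_start, extended),
#'   `activity`, `qos`, `weights`, `newly_registered`, `lda`, `target_vector`,
#'   `corpus`, `embeddings`, `config`.
#' @export
run_pipeline <- function(consultations, profiles, knowledge, dicts,
                         target_text, weights = preference_weights("Fair",
                                                                   "Fair"),
                         config = pipeline_config(), stages_only = FALSE) {
  stopifnot(inherits(config, "specrec_config"))
  if (is.character(consultations) && length(consultations) == 1)
    consultations <- read_consultations(consultations)
  if (is.character(weights) && length(weights) == 2)
    weights <- preference_weights(weights[1], weights[2])

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- stage 0: preprocessing -------------------------------------------------
  corpus <- run_stage("preprocess", build_corpus(consultations, dicts))
  target_tokens <- run_stage("preprocess",
                             tokenize(normalize_text(target_text, dicts),
                                      dicts))

  # -- stage 1: patient feature model / initial candidates --------------------
  initial <- run_stage("patient_model", {
    train_docs <- c(corpus$documents, list(.target = target_tokens))
    emb <- train_embeddings(train_docs, dimension = config$embedding_dim,
                            window = config$embedding_window,
                            negative = config$embedding_negative,
                            epochs = config$embedding_epochs,
                            seed = config$seed)
    tfidf <- tfidf_weights(corpus)
    dvecs <- corpus_doc_vectors(corpus, emb, tfidf)
    tvec <- target_doc_vector(target_tokens, emb, tfidf)
    doc_spec <- stats::setNames(corpus$meta$specialist_id, corpus$meta$doc_id)
    list(candidates = generate_candidates(tvec, dvecs, doc_spec,
                                          n = config$n_candidates),
         embeddings = emb, tfidf = tfidf, doc_vectors = dvecs,
         target_vector = tvec)
  })

  # -- stage 2: long-term knowledge cold-start repair -------------------------
  km <- run_stage("knowledge_long", {
    km <- impute_matrix(knowledge)
    if (config$knowledge_weights == "rarity")
      km <- knowledge_matrix(km$values, rarity_weights(km))
    km
  })
  newly <- newly_registered(
    consultations, specialists = rownames(km$values),
    max_consultations = config$newcomer_max_consultations)
  after_cold <- run_stage("knowledge_long",
                          update_cold_start(initial$candidates, km, newly,
                                            config$sim_knowledge_threshold))

  # -- stage 3: short-term knowledge topic-space extension --------------------
  ext <- run_stage("knowledge_short", {
    sdocs <- specialist_documents(corpus)
    K <- if (!is.null(config$k_grid))
      as.integer(select_topic_count(sdocs, config$k_grid,
                                    alpha = config$lda_alpha,
                                    beta = config$lda_beta,
                                    seed = config$seed))
    else config$lda_k
    K <- min(K, length(unique(unlist(sdocs, use.names = FALSE))))
    lda <- fit_lda(sdocs, K, alpha = config$lda_alpha,
                   beta = config$lda_beta,
                   iterations = config$lda_iterations, seed = config$seed)
    profs <- lda$theta
    # candidates without any diagnosed EMR (cold-start inserts) have no
    # document-topic row; give them the uniform distribution
    miss <- setdiff(after_cold$specialist_id, rownames(profs))
    if (length(miss)) {
      uni <- matrix(1 / K, length(miss), K,
                    dimnames = list(miss, colnames(profs)))
      profs <- rbind(profs, uni)
    }
    list(candidates = extend_candidates(after_cold, profs,
                                        min_sim = config$extension_min_sim,
                                        per_seed_cap = config$extension_cap),
         lda = lda, profiles = profs)
  })

  # -- stage 4: activity + QoS fusion -----------------------------------------
  scoring <- run_stage("scoring", {
    ledger <- activity_ledger(consultations,
                              horizon = config$activity_horizon,
                              specialists = sort(union(
                                unique(consultations$specialist_id),
                                ext$candidates$specialist_id)))
    act <- activity_scores(ledger)
    qos <- qos_scores(tibble::tibble(specialist_id = profiles$specialist_id,
                                     qos = profiles$qos))
    list(activity = act, qos = qos)
  })

  out <- structure(list(
    recommendation = NULL,
    stages = list(initial = initial$candidates, cold_start = after_cold,
                  extended = ext$candidates),
    activity = scoring$activity, qos = scoring$qos, weights = weights,
    newly_registered = newly, lda = ext$lda,
    topic_profiles = ext$profiles,
    target_vector = initial$target_vector,
    doc_vectors = initial$doc_vectors,
    corpus = corpus, embeddings = initial$embeddings,
    config = config), class = "specrec_run")
  if (stages_only) return(out)
  out$recommendation <- run_stage("scoring",
                                  hybrid_rank(ext$candidates,
                                              scoring$activity, scoring$qos,
                                              weights,
                                              n = config$n_candidates))
  out
}

#' Re-fuse a finished pipeline run under different preference weights
#'
#' The candidate pool, activity and QoS components of a `specrec_run` are
#' weight-independent, so sweeping the subjective preference weights only
#' requires repeating the linear fusion.
#'
#' @param run a `specrec_run` from [run_pipeline()].
#' @param weights a `specrec_weights` object.
#' @param n list size (default: the run's configured size).
#' @return A `specrec_recommendation` tibble.
#' @export
refuse_weights <- function(run, weights, n = NULL) {
  stopifnot(inherits(run, "specrec_run"))
  if (is.null(n)) n <- run$config$n_candidates
  hybrid_rank(run$stages$extended, run$activity, run$qos, weights, n = n)
}

#' @export
print.specrec_run <- function(x, ...) {
  cat("<specrec_run>\n  candidates: initial", nrow(x$stages$initial),
      "-> cold-start", nrow(x$stages$cold_start),
      "-> extended", nrow(x$stages$extended), "\n")
  if (!is.null(x$recommendation)) {
    cat("  top", nrow(x$recommendation), "recommendation (omega_p =",
        format(x$weights$omega_p, digits = 3), "):\n")
    print(as.data.frame(x$recommendation), digits = 3)
  }
  invisible(x)
}

#' Mean specialist vectors in the EMR embedding space
#'
#' Aggregate document vector per specialist (the mean of their diagnosed
#' EMRs' vectors), used by the relevance metric.
#'
#' @param run a `specrec_run`.
#' @param specialist_ids which specialists (default: all with documents).
#' @return matrix of specialist vectors.
#' @export
specialist_vectors <- function(run, specialist_ids = NULL) {
  meta <- run$corpus$meta
  if (is.null(specialist_ids)) specialist_ids <- sort(unique(meta$specialist_id))
  out <- t(vapply(specialist_ids, function(s) {
    ids <- meta$doc_id[meta$specialist_id == s]
    if (!length(ids)) stop("specialist has no documents: ", s)
    colMeans(run$doc_vectors[ids, , drop = FALSE])
  }, numeric(ncol(run$doc_vectors))))
  rownames(out) <- specialist_ids
  out
}
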