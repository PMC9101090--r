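# Shared fixtures, built in code. The small world/config keep unit tests
# fast; acceptance checks use the generator defaults.

small_world <- function(seed = 7L, ...) {
  generate_world(world_config(n_specialists = 20L, n_patients = 150L,
                              seed = seed, ...))
}

small_config <- function(seed = 7L, ...) {
  pipeline_config(lda_k = 5L, lda_iterations = 150L, embedding_dim = 32L,
                  embedding_epochs = 10L, seed = seed, ...)
}

# a tiny deterministic candidate set for knowledge-stage tests
toy_candidates <- function(ids = c("A", "B"), ini = c(0.5, 0.4)) {
  specrec:::new_candidate_set(tibble::tibble(
    specialist_id = ids, ini_score = ini,
    provenance = "patient-similarity", short_score = NA_real_))
}

random_distribution <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}
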