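# specrec — self-adaptive telemedicine specialist recommendation

`specrec` recommends telemedicine specialists to a patient from the free
text of electronic medical records (EMRs), for settings where almost no
explicit doctor ratings exist (data sparsity), newly registered specialists
have no history (cold start), and privacy rules leave only a handful of
consultation attributes available. Its intended users are researchers and
platform engineers studying content-based clinical recommendation; it ships
with a fully synthetic world generator, so every stage can be exercised and
validated without access to any clinical data.

## The method

Given a consultation log, specialist profiles and a target patient's EMR,
the pipeline runs four stages, each of which leaves an auditable candidate
set:

1. **Patient feature model.** After synonym normalization, dictionary-aware
   tokenization and stop-word filtering, each EMR *d* becomes a TF-IDF
   weighted average of skip-gram word embeddings over its *f* distinct
   feature words:

   d = (1/f) · Σₖ v_k · tfidf(w_k, d),  tf = count/|d|, idf = ln(N/df).

   Specialists who treated patients similar to the target (cosine
   similarity of EMR vectors) form the initial candidate set; each
   specialist's `ini_score` is the *highest* similarity among their
   patients, and the top 10 are retained.

2. **Long-term knowledge (cold-start repair).** Specialists' disease
   expertise is a binary attribute matrix (missing cells imputed by a
   column-frequency rule). For each newly registered specialist *j* (fewer
   than three consultations), candidate-set members *h* with weighted
   Jaccard similarity SimKnowledge(j,h) ≥ 0.7 contribute

   ini_score′_j = ini_score_j + (1/q) Σₕ ini_scoreₕ · SimKnowledge(j,h),

   and *j* joins the candidate set.

3. **Short-term knowledge (topic-space extension).** A collapsed-Gibbs LDA
   topic model is fitted over per-specialist documents (the concatenation of
   the EMRs each specialist diagnosed). Specialists whose document–topic
   distributions are close to a candidate's — similarity 1 − D_JS with the
   Jensen–Shannon divergence taken base 2 — extend the set with
   `short_score` equal to that similarity.

4. **Activity + feedback fusion.** Per-specialist activity decays with
   period age t (months): AC_j = Σₜ N_j(t)·e^(−t)/N(t), LAC_j = AC_j/AC_max.
   The professional index is prof_score = LAC × ini_score × short_score, and
   the final ranking fuses it with the normalized mean service rating
   (objective QoS):

   compre_score = ω_p · prof_score′ + ω_q · qos_score,

   where the subjective preference weights (ω_p, ω_q) come from two
   questionnaire answers mapped 4/3/2/1/0 (e.g. "Extremely like" +
   "Like" → ω_p = 4/7, ω_q = 3/7).

Evaluation helpers compute Pre@N / Rec@N against label sets, mean relevance
in the embedding space, and rank-weighted rationality scores.

## A worked example

```r
library(specrec)
world <- generate_world(world_config(n_specialists = 30, n_patients = 400, seed = 11))
run <- run_pipeline(world$consultations, world$profiles, world$knowledge,
                    world$dicts, world$target$text,
                    weights = preference_weights("Extremely like", "Like"),
                    config = pipeline_config(seed = 11))
print(run)
```

```
<specrec_run>
  candidates: initial 10 -> cold-start 10 -> extended 13
  top 10 recommendation (omega_p = 0.571 ):
   specialist_id         provenance ini_score short_score     lac prof_score
1           S016 patient-similarity     0.957       1.000 0.28839    0.27599
2           S006 patient-similarity     0.923       1.000 0.16897    0.15602
3           S027 patient-similarity     0.931       1.000 0.17361    0.16167
4           S007    topic-extension     0.950       0.842 0.13453    0.10760
5           S008 patient-similarity     0.965       1.000 0.05638    0.05441
6           S030         cold-start     1.930       1.000 0.01031    0.01031
...
```

Reading the output: the stage log shows the candidate pool growing from the
10 patient-similarity retrievals through cold-start insertion to 13 after
topic-space extension. Each recommended specialist carries every component
score — S016 leads because it combines a high EMR similarity (`ini_score`
0.957) with the largest time-decayed activity share of the pool and a good
rating; S030 is a newly registered specialist whose index was repaired from
an almost identical knowledge profile (`cold-start` provenance); S007
entered purely through topic-distribution similarity (`topic-extension`,
`short_score` 0.842). Nine of these ten specialists are, per the generator's
ground truth, specialized in the target patient's disease topic:

```r
sum(run$recommendation$specialist_id %in% world$truth$best_match)
#> [1] 9
```

A shell front end with `simulate`, `recommend`, `topics` and `evaluate`
subcommands is installed under `<library>/specrec/cli/specrec`.

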