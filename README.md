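# eventseg

Automated event segmentation and embedding-based recall scoring for
narrative text.

## The problem

Readers spontaneously carve a continuous narrative into discrete *events*,
and the boundaries they perceive structure what they later remember.
Studying this usually takes two expensive human steps: cohorts of raters
marking boundaries between words, and trained raters scoring free-recall
transcripts event by event on a 0-10 gist scale. `eventseg` is for memory
and language researchers who want to automate both steps and to quantify,
with the field's agreement statistics, how well the automated judgments
track human ones:

- **Segmentation**: a chat-completion model is prompted to copy a story
  word-for-word, starting a new line wherever one event ends. Each of the
  (default 20) independent runs is an *instance*, treated like one
  participant. Completions are aligned back to the original text, so
  imperfect copies still yield boundary positions in the narrative's own
  word coordinates.
- **Recall scoring**: narrative and recall are segmented into events and
  embedded; recall quality is read off a narrative-by-recall Spearman
  similarity matrix.

Model access is injected (any `function(prompt, temperature, max_tokens,
instance_index)` and any `function(texts) -> matrix`), and the package
bundles a deterministic mock client and fixture embedder, so the entire
pipeline runs and is validated offline.

## The statistics

For rater *i* with binary word-level series `x_i` (1 where a boundary
precedes the word) and the leave-one-out group profile
`p_{-i} = mean(x_j, j != i)`:

- **Agreement index**: the point-biserial correlation `r(x_i, p_{-i})`,
  which for a continuous profile is the Pearson correlation.
- **Shared vs. distinct boundaries**: a human boundary position is *shared*
  if any model instance marks the same position; group amplitudes at shared
  and distinct positions are compared.
- **Between-group consistency**: over 100 random splits (two human groups
  of 10, one sampled model group of 10), the proportion of the main group's
  profile peaks found in the comparison group's peaks, with the smaller
  peak set as denominator.
- **Recall scores**: `S[i, j] = spearman(e_narr_i, e_recall_j)` resized
  bilinearly to the narrative's event count; the row maximum is the
  event-level score and its mean the narrative score, referenced against
  the same pipeline run on unrelated narratives (baseline).
- **Intersubject agreement**: diagonal vs. reverse-diagonal means of
  pairwise recall-by-recall matrices (same vs. reversed temporal order).
- **Split-half reliability**: participants split in half; actual Spearman
  correlation between automated and human scores in one half, shuffled null
  in the other, 10,000 iterations; one-tailed add-one permutation p and the
  Spearman-Brown correction `rho_SB = 2 * rho / (1 + rho)`.

## Worked example

A fully synthetic study: 20 simulated human segmenters (hit rate 0.7,
1-word jitter, 2 false alarms per 1000 words) and 20 mock model instances
per temperature around 13 latent boundaries in a 1500-word narrative.

```r
library(eventseg)

study <- simulate_segmentation_study(seed = 42)
wc <- study$narrative$word_count
human_series <- lapply(study$human_responses, to_series, word_count = wc)
llm0_series  <- lapply(study$llm_runs[["0"]]$responses, to_series, word_count = wc)

human_agree <- agreement_indices(human_series)
llm0_agree  <- agreement_indices(llm0_series)
sprintf("mean agreement: humans %.3f, model instances (temp 0) %.3f",
        mean(human_agree$agreement), mean(llm0_agree$agreement))
#> mean agreement: humans 0.330, model instances (temp 0) 1.000

sd_tab <- classify_shared_distinct(group_profile(human_series), llm0_series)
sprintf("human amplitude at shared vs distinct boundaries: %.3f vs %.3f",
        mean(sd_tab$human_proportion[sd_tab$label == "shared"]),
        mean(sd_tab$human_proportion[sd_tab$label == "distinct"]))
#> human amplitude at shared vs distinct boundaries: 0.285 vs 0.089

cons <- split_permutation_consistency(human_series, llm0_series, seed = 42)
sprintf("consistency: human-vs-human %.3f, human-vs-model %.3f",
        mean(cons$proportion[cons$comparison == "human_vs_human"]),
        mean(cons$proportion[cons$comparison == "human_vs_llm"]))
#> consistency: human-vs-human 0.184, human-vs-model 0.580
```

The noiseless temperature-0 mock reproduces the latent boundaries exactly,
so its instances agree perfectly (1.000) while the noisy human cohort
agrees at 0.330; boundary positions the model shares with humans are the
high-consensus ones (amplitude 0.285 vs 0.089); and a human group's peaks
are found more reliably in the model group than in a second human group
(0.580 vs 0.184), because averaging noiseless instances concentrates the
profile on the true boundaries.

Recall scoring with the fixture embedder, one participant at fidelity 0.8:

```r
embedder <- fixture_embedder(dim = 256, seed = 42)
narr_set <- embed_segments(segment_texts(study$narrative, study$ground_truth),
                           embedder, owner_id = "narr",
                           narrative_id = study$narrative$id)
narr_set$vectors <- narr_set$vectors / sqrt(rowSums(narr_set$vectors^2))
recall <- simulate_recall(narr_set, recall_model(0.8, embed_dim = 256, seed = 43), "p01")
other <- embed_segments(segment_texts(synthetic_narrative(1500, seed = 99, id = "other"),
                                      simulate_ground_truth(1500, 13, 20, seed = 99)),
                        embedder, owner_id = "other", narrative_id = "other")
sc <- score_recall(narr_set, recall)
bl <- baseline_scores(recall, list(other))
sprintf("recall score %.3f vs baseline %.3f", sc$narrative_score, bl$narrative_score)
#> recall score 0.781 vs baseline 0.617

spearman_brown(0.5)
#> [1] 0.6666667
```

The recall built from the true events scores well above the same recall
scored against an unrelated narrative.

File-based workflows (`cmd_segment`, `cmd_boundaries`, `cmd_recall`,
`cmd_simulate`) mirror these analyses over CSV/JSON tables and write a
manifest per run; `inst/cli/eventseg.R` exposes them as a command-line
script. See `vignette("eventseg-methods")` for the modeling choices and
their rationale.

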