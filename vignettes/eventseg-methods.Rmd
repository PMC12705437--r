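---
title: "Methods: automated event segmentation and recall scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated event segmentation and recall scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

People segment continuous narratives into discrete events, and the
boundaries they perceive organize later recall. Measuring this normally
requires cohorts of human raters to mark boundaries by hand and trained
raters to score free-recall transcripts event by event -- slow, costly, and
rater-dependent. `eventseg` implements an automated pipeline: a
chat-completion model segments the narrative through a copy-and-break
prompt, text embeddings score recall by semantic similarity to the
segmented events, and a family of agreement, consistency, and reliability
statistics quantifies how well the automated judgments track human ones.

This vignette documents the models and procedures, the parameters that
matter, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the methods left the details open.

# Boundary coordinates

All analyses live in a single coordinate frame. A narrative is tokenized
into words (maximal runs of non-whitespace; punctuation stays attached).
Word indices are 0-based. A boundary `b` in `[1, word_count - 1]` means
"one event ends just before token `b`": raters draw lines *between* two
words, so the narrative onset (index 0) and offset are not representable
boundaries. Event spans are half-open `[start, end)` token ranges, so any
boundary set partitions the narrative exactly.

The per-rater **word-level series** is a binary vector over words: 1 where
a boundary was identified just prior to that word. The **group profile** is
the element-wise mean across raters; its amplitude at a word is the
proportion of raters marking a boundary there.

# Prompted segmentation

The segmentation prompt is fixed: an instruction paragraph that defines an
event as an ongoing coherent situation and asks for a word-for-word copy of
the story with a new line wherever one event ends, then the narrative, then
a closing line announcing the segmented copy. `run_instances()` submits the
prompt `n_instances` times (default 20, one instance per pseudo-participant)
at a configured temperature in `[0, 1]` with a completion budget
(`max_tokens`, default 4096 -- enough for a full copy of a ~1500-word
narrative).

Clients are injected functions, so hosted APIs and the bundled
deterministic mock share one contract. Two client-facing choices:

* **Temperature floor.** Some backends forbid an exact temperature 0; the
  request is sent at `temperature_floor` (for example 0.1) but the
  condition is *labeled* with the nominal temperature, keeping conditions
  comparable across providers.
* **Retries.** Client errors are retried with capped exponential backoff up
  to `max_retries`; persistent failures are recorded per instance, and a run
  fails only if every instance fails. Keeping the retry budget small also
  keeps redundant API traffic down.

**Parsing segmented copies.** A model's completion is mapped back to the
original narrative's coordinates. For a byte-identical copy (after
whitespace normalization) the mapping is positional. Otherwise tokens are
normalized (lowercased, punctuation stripped) and the copy is globally
aligned to the original with unit match/mismatch/indel scores
(Needleman-Wunsch over tokens); traceback prefers diagonal, then vertical
moves, which resolves ties toward the earliest alignment. Each newline
inherits the original index aligned to the copy token that follows it;
newlines before unaligned (inserted) tokens, or before the first word, are
dropped with a logged message. The fraction of original tokens matched is
the copy's *fidelity*; below `min_fidelity` (default 0.95) the response is
rejected as a degraded copy rather than trusted. The threshold is a design
choice: the prompt asks for word-for-word copies, real models occasionally
paraphrase, and a copy missing more than one word in twenty no longer
anchors boundary positions credibly.

# Boundary statistics

* **Agreement index.** The point-biserial correlation between one rater's
  binary series and the mean series of all *other* raters in the group
  (leave-one-out). With a continuous reference the point-biserial reduces
  to the Pearson product-moment correlation, which is what is computed.
  Raters with constant series (no boundaries, or boundaries everywhere)
  have undefined correlations; they are flagged and excluded from group
  summaries with a log entry rather than silently dropped or imputed.
  Human-to-model agreement uses the same statistic with the full model
  group profile as the reference (no leave-one-out, since the target is
  not part of the reference group).
* **Boundary rate.** Counts are scaled per 1000 words so narratives of
  different lengths are comparable.
* **Shared vs. distinct boundaries.** Every position with positive human
  amplitude is *shared* if at least one model instance marked the same
  location, else *distinct*. Matching is exact-position by default; a
  tolerance window (in words) is exposed for sensitivity analysis but
  defaults to 0 because exactness is reproducible.
* **Peaks.** A peak of a group profile is a positive local maximum with the
  series edges treated as minus-infinity flanks. A plateau (a run of equal
  values exceeding both flanks) contributes exactly one peak at its first
  index. The plateau rule is a stated convention -- "peak" is otherwise
  underdetermined -- and the first index keeps the rule order-stable.
* **Normative boundaries.** The group's consensus set: the `n` positions
  with the largest amplitudes, where `n` is the mean per-rater boundary
  count rounded half-to-even (the rounding rule is a stated choice; ties in
  amplitude break toward the earlier index and are logged).

# Between-group consistency

`split_permutation_consistency()` asks how often one group's event
boundaries reappear in another group's. Per iteration the human cohort is
split at random into a main and a comparison group of `group_size` (default
10 of 20), and `group_size` model instances are drawn from the model pool.
Each group's profile is averaged and its peaks taken as the group's
boundaries; the match proportion divides matched boundaries by the size of
the *smaller* set, since groups rarely produce equal event counts. Both
comparisons (main vs. human comparison, main vs. model comparison) share
the same main-group draw within an iteration, making them paired -- the
procedure implies but does not require this; pairing reduces
between-iteration noise in the contrast. Default 100 iterations. With a
positive tolerance, matching is greedy one-to-one in sorted order; at the
default tolerance 0 it is plain set intersection. The iteration table is
fully reproducible from the seed, with a documented draw order (human
permutation, then model draw).

# Recall scoring

Narrative and recall texts are segmented into events, each segment is
embedded into a vector, and cell `(i, j)` of the similarity matrix is the
Spearman correlation between narrative segment `i` and recall segment `j`.
Rank correlation is used instead of cosine similarity because it is less
sensitive to outlying embedding dimensions.

Because participants produce different numbers of recall events, the
matrix is resized to `n x n`, where `n` is the narrative's event count,
by bilinear interpolation of the matrix viewed as an image -- pixel-center
convention (output pixel `i` samples source coordinate
`(i + 0.5) * nin/nout - 0.5`), edge clamping, no smoothing or
anti-aliasing -- and clamped to `[-1, 1]`. Resizing an `n x n` matrix to
`n x n` is the identity. The interpolation convention is the
compatibility-sensitive choice here: different image libraries disagree at
the half-pixel level, so the convention is fixed, documented, and tested
against an independently coded cell-by-cell oracle.

From the square matrix, the row maximum is the event-level recall score
(the best-matching recalled event for each narrative event) and the mean of
row maxima is the narrative recall score. The **baseline** runs the same
pipeline against unrelated narratives and averages the resulting narrative
scores -- computed per narrative and then averaged, rather than pooling
events before the max, because the per-narrative pipeline is the unit the
actual score uses. Undefined correlations (constant embedding vectors)
propagate as missing values and are excluded from means with logged counts,
never imputed.

**Intersubject agreement.** For each ordered pair of participants, the
recall-by-recall similarity matrix is resized to the narrative's event
count; the main diagonal measures recalling in the same order as the other
participant, the reverse diagonal recalling in reverse order (the control).
Each participant's diagonal and reverse-diagonal means are averaged over
their N-1 pairings. Ordered pairs are used (each participant is averaged
over their own pairings), which the N-1-per-participant summary implies.

**Standardization.** Scores are z-transformed within each embedding-model
group (sample SD) so magnitudes are comparable across models.

**Embedders are injected.** Any `function(texts) -> matrix` works. The
bundled `fixture_embedder()` is a seeded random projection of hashed token
counts: deterministic, offline, and it preserves lexical-overlap structure
(texts sharing words get correlated vectors). It is a test fixture, not a
semantic model -- paraphrases with disjoint vocabulary are unrelated under
it -- so validation with it exercises the *pipeline*, not the semantics of
any particular embedding model.

# Reliability statistics

**Split-half consistency** between automated and human gist scores: per
iteration, participants are divided randomly into two equal halves (an odd
cohort puts the extra participant in the first half, logged). In the first
half the Spearman correlation between concatenated automated and human
event-level scores is an "actual" value; in the second half the human
scores are shuffled before correlating, a "null" value. Default 10,000
iterations. The one-tailed permutation p compares the *mean* actual
correlation against the null distribution with the add-one rule
`(count + 1) / (iterations + 1)`, so p is never exactly zero. The
Spearman-Brown correction `2 * rho / (1 + rho)` of the mean actual
correlation adjusts for the halved sample.

Two stated choices: the add-one rule (the permutation-p convention that
avoids zero p-values), and the shuffle unit -- by default human scores are
permuted across *all* triples in the null half; a within-participant
alternative is exposed as `shuffle_unit = "within_participant"` since the
procedure's description does not fix the unit.

One property of this statistic is worth knowing and is measured by the test
suite: because the p-value compares the tightly concentrated *mean* of the
actual correlations against *single-draw* half-sample nulls, the test is
conservative under independence -- its measured type-I rate at a nominal
alpha of 0.05 sits near 0.01 rather than 0.05 in the suite's simulations.
It under-rejects, never over-rejects, so significant results are if
anything understated.

**Boundary validation ratings.** Raters judge marked positions as true
boundaries or not with a 1-10 confidence; ratings are sign-coded
(no-responses negative) and scaled by a factor of 1/10 into `[-1, 1]`, so
-1 is high confidence in a non-boundary and values near 0 are low
confidence either way. The sign-then-scale map is one of several readings
of "linearly scaled"; it is exposed as the single place the scaling is
implemented. Per-participant means feed a one-sample t against zero per
condition and a pooled-variance two-sample t between conditions.

# Synthetic cohorts

The generators produce data with exactly the structure the analyses
assume; all are pure functions of their parameters and seed.

* **Ground truth**: boundary positions sampled uniformly with a minimum
  separation (defaults 13 boundaries, 20-word separation in a 1500-word
  narrative -- the scale of the study conditions: ~1500-word chapters with
  a median of 13 events).
* **Segmenters**: each true boundary detected with probability `hit_rate`,
  displaced by rounded Gaussian jitter (clipped; collisions re-drawn), plus
  Poisson false alarms at `fa_per_1000`. Gaussian jitter and Poisson false
  alarms are the simplest noise family consistent with the variability the
  task produces. The default human cohort uses hit rate 0.7, jitter SD 1
  word, 2 false alarms per 1000 words: a cohort that finds most but not all
  consensus boundaries, occasionally one word off, with a few idiosyncratic
  marks.
* **Mock generation client**: returns a word-for-word copy with newlines at
  simulate-rater-perturbed positions. The default temperature map is
  temperature 0 = (hit 1.0, jitter 0, false alarms 0) -- functionally
  deterministic -- with higher temperatures degrading detection and adding
  false alarms (0.5 = (0.9, 1, 2); 1 = (0.8, 2, 6)), so higher temperatures
  also produce *more* boundaries, the direction observed with real models.
* **Recalls**: per event, with probability `omit_prob` the event is
  skipped; otherwise the recall vector is
  `alpha * event + sqrt(1 - alpha^2) * noise` renormalized, so `alpha` is
  the expected correlation with the true event at high dimension. Adjacent
  events swap with probability `order_swap_prob` in one pass.
* **Gist raters**: `gist = clamp(round(10 * fidelity + N(0, noise_sd)), 0, 10)`.

What the generators do *not* emulate: linguistic content (synthetic
narratives are structural filler), systematic rater biases (anchoring,
fatigue), semantically graded confusions between similar events, and any
relationship between narrative position and boundary salience. Passing
tests therefore demonstrate that the statistics recover known structure
from data satisfying their assumptions -- not that any particular language
or embedding model segments or scores well on real narratives.

# Numerical choices and degenerate inputs

* Correlations against constant vectors are errors with a dedicated
  condition class (`eventseg_undefined_correlation`); drivers catch them,
  flag the rater/segment, and continue.
* `normative_boundaries` with fewer positive-amplitude positions than
  requested returns all positive positions with a warning.
* All-zero profiles have no peaks (warning, empty set); permutation
  iterations whose groups have no peaks are skipped for that comparison and
  logged.
* Boundary indices read from CSV tolerate float formatting (`"3.0"`) with a
  warning; genuine non-integers are errors naming row and column.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state, so library calls never perturb user randomness.

# Problem sizes used by the test suite

The suite validates at the study's cohort scale (20 raters, 20 instances,
groups of 10, 100 permutation iterations) while choosing narrative lengths
per test: full 1500-word narratives where a single run is checked, and
300-500-word narratives with proportionally fewer boundaries where a
property is replicated across 100+ simulated studies. Split-half
reliability is validated at 10,000 iterations once (null stability across
seeds) and at 1,000 iterations across 500 datasets for the type-I
measurement. These sizes are the package's validation design: large enough
for the asymptotics the statistics rely on, small enough to replicate
heavily.

# Limitations

* The pipeline scores gist-level semantic similarity; verbatim accuracy and
  detail counts need different instruments.
* Real chat models produce imperfect copies; the alignment-based parser
  recovers boundaries up to the fidelity threshold, but systematic
  paraphrasing beyond it discards instances (recorded, never silently).
* The fixture embedder validates plumbing, not semantics; conclusions about
  a specific embedding model require injecting it.
* The split-half permutation test is conservative under independence (see
  above).
* Exact-position boundary matching is strict for long narratives; the
  tolerance window exists for sensitivity analysis, with greedy one-to-one
  matching once positive.
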