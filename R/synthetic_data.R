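# Synthetic cohorts with the statistical structure the analyses assume:
# latent normative boundaries shared by noisy segmenters (parametric hit
# rate, positional jitter, false alarms), recall embeddings with controlled
# semantic fidelity and temporal order, gist ratings correlated with true
# fidelity, and a deterministic mock generation client. Every generator is a
# pure function of its parameters and seed.

#' Segmenter noise model
#'
#' Operationalizes rater variability around latent normative boundaries:
#' each true boundary is detected with probability `hit_rate`, detected
#' boundaries are displaced by rounded Gaussian jitter, and spurious
#' boundaries arrive as a Poisson count proportional to narrative length.
#'
#' @param hit_rate Detection probability in `[0, 1]`.
#' @param jitter_sd Positional jitter standard deviation in words.
#' @param fa_per_1000 Expected false alarms per 1000 words.
#' @param seed Optional seed making [simulate_rater()] deterministic.
#' @return List of class `eventseg_segmenter_model`.
#' @export
segmenter_model <- function(hit_rate, jitter_sd = 0, fa_per_1000 = 0,
                            seed = NULL) {
  if (hit_rate < 0 || hit_rate > 1 || jitter_sd < 0 || fa_per_1000 < 0) {
    es_error("invalid segmenter model parameters", "eventseg_invalid_input")
  }
  structure(list(hit_rate = hit_rate, jitter_sd = jitter_sd,
                 fa_per_1000 = fa_per_1000, seed = seed),
            class = "eventseg_segmenter_model")
}

#' Recall noise model
#'
#' Controls how faithfully simulated recall embeddings track the narrative's
#' event embeddings: fidelity `alpha` mixes each event vector with fresh
#' unit noise, events are omitted independently, and adjacent recalled
#' events swap order with a given probability.
#'
#' @param fidelity_alpha Mixing weight in `[0, 1]` on the true event vector.
#' @param order_swap_prob Probability of swapping each adjacent pair.
#' @param omit_prob Probability an event is not recalled.
#' @param embed_dim Embedding dimension (at least 8).
#' @param seed Optional seed.
#' @return List of class `eventseg_recall_model`.
#' @export
recall_model <- function(fidelity_alpha, order_swap_prob = 0, omit_prob = 0,
                         embed_dim = 256L, seed = NULL) {
  probs <- c(fidelity_alpha, order_swap_prob, omit_prob)
  if (any(probs < 0) || any(probs > 1) || embed_dim < 8L) {
    es_error("invalid recall model parameters", "eventseg_invalid_input")
  }
  structure(list(fidelity_alpha = fidelity_alpha,
                 order_swap_prob = order_swap_prob, omit_prob = omit_prob,
                 embed_dim = as.integer(embed_dim), seed = seed),
            class = "eventseg_recall_model")
}

#' Sample latent normative boundaries
#'
#' Uniformly samples `n_boundaries` valid boundary indices with pairwise
#' separation at least `min_separation` words.
#'
#' @param word_count Narrative length in words.
#' @param n_boundaries Number of boundaries.
#' @param min_separation Minimum gap between boundaries in words.
#' @param seed Optional seed.
#' @return Sorted 0-based integer indices in `[1, word_count - 1]`.
#' @export
simulate_ground_truth <- function(word_count, n_boundaries,
                                  min_separation = 1L, seed = NULL) {
  if (n_boundaries < 1L || min_separation < 1L) {
    es_error("need n_boundaries >= 1 and min_separation >= 1",
             "eventseg_invalid_input")
  }
  # shift trick: sample strictly increasing values, then open the gaps
  slots <- (word_count - 1L) - (n_boundaries - 1L) * (min_separation - 1L)
  if (n_boundaries * min_separation >= word_count || slots < n_boundaries) {
    es_error("infeasible: too many boundaries for this word count and separation",
             "eventseg_invalid_input")
  }
  with_seed(seed, {
    base <- sort(sample.int(slots, n_boundaries))
    as.integer(base + (seq_len(n_boundaries) - 1L) * (min_separation - 1L))
  })
}

#' Simulate one rater's segmentation of a narrative
#'
#' Each ground-truth boundary is kept with probability `hit_rate` and
#' displaced by rounded Gaussian jitter (clipped into the valid range;
#' collisions re-drawn, falling back to the nearest free position). False
#' alarms are added as a Poisson count with mean
#' `fa_per_1000 * word_count / 1000` at uniformly chosen free positions.
#'
#' @param gt Ground-truth boundary indices.
#' @param model An `eventseg_segmenter_model`.
#' @param word_count Narrative length.
#' @param rater_id,source,condition,narrative_id Labels for the response.
#' @return An `eventseg_response`.
#' @export
simulate_rater <- function(gt, model, word_count, rater_id = "sim",
                           source = "human", condition = "sim",
                           narrative_id = "synthetic") {
  stopifnot(inherits(model, "eventseg_segmenter_model"))
  gt <- validate_boundaries(gt, word_count)
  with_seed(model$seed, {
    kept <- gt[stats::runif(length(gt)) < model$hit_rate]
    marks <- integer(0)
    for (b in kept) {
      pos <- b + as.integer(round(stats::rnorm(1, 0, model$jitter_sd)))
      pos <- min(max(pos, 1L), word_count - 1L)
      tries <- 0L
      while (pos %in% marks && tries < 20L) {
        pos <- b + as.integer(round(stats::rnorm(1, 0, model$jitter_sd)))
        pos <- min(max(pos, 1L), word_count - 1L)
        tries <- tries + 1L
      }
      if (pos %in% marks) {
        free <- setdiff(seq_len(word_count - 1L), marks)
        if (length(free) == 0L) next
        pos <- free[which.min(abs(free - b))]
      }
      marks <- c(marks, pos)
    }
    n_fa <- stats::rpois(1, model$fa_per_1000 * word_count / 1000)
    if (n_fa > 0L) {
      free <- setdiff(seq_len(word_count - 1L), marks)
      if (length(free)) {
        marks <- c(marks, sample(free, min(n_fa, length(free))))
      }
    }
    segmentation_response(rater_id, source, condition, narrative_id,
                          sort(marks), word_count = word_count)
  })
}

#' Simulate a recall embedding set from narrative embeddings
#'
#' Per narrative event: with probability `omit_prob` the event is skipped;
#' otherwise the recall vector is
#' `alpha * event + sqrt(1 - alpha^2) * noise`, renormalized, with `noise` a
#' fresh unit Gaussian vector. Adjacent emitted events are then swapped with
#' probability `order_swap_prob` in one left-to-right pass.
#'
#' @param narr_set Narrative embedding set with unit-normalized rows.
#' @param model An `eventseg_recall_model`.
#' @param owner_id Participant identifier for the simulated recall.
#' @return An `eventseg_embedding_set`.
#' @export
simulate_recall <- function(narr_set, model, owner_id = "sim") {
  stopifnot(inherits(narr_set, "eventseg_embedding_set"),
            inherits(model, "eventseg_recall_model"))
  norms <- sqrt(rowSums(narr_set$vectors^2))
  if (any(abs(norms - 1) > 1e-6)) {
    es_error("narrative embeddings must be unit-normalized",
             "eventseg_invalid_input")
  }
  d <- narr_set$dim
  a <- model$fidelity_alpha
  with_seed(model$seed, {
    vecs <- list()
    src <- integer(0)
    for (i in seq_len(narr_set$n_segments)) {
      if (stats::runif(1) < model$omit_prob) next
      z <- stats::rnorm(d)
      z <- z / sqrt(sum(z^2))
      v <- a * narr_set$vectors[i, ] + sqrt(1 - a^2) * z
      v <- v / sqrt(sum(v^2))
      vecs[[length(vecs) + 1L]] <- v
      src <- c(src, i)
    }
    if (length(vecs) == 0L) {
      es_error("all events omitted from simulated recall", "eventseg_invalid_input")
    }
    ord <- seq_along(vecs)
    if (length(ord) > 1L) {
      for (i in seq_len(length(ord) - 1L)) {
        if (stats::runif(1) < model$order_swap_prob) {
          ord[c(i, i + 1L)] <- ord[c(i + 1L, i)]
        }
      }
    }
    embedding_set(owner_id, narr_set$narrative_id,
                  sprintf("<recalled event %d>", src[ord]),
                  do.call(rbind, vecs[ord]))
  })
}

#' Simulate human gist ratings from true per-event fidelities
#'
#' `gist = clamp(round(10 * fidelity + N(0, noise_sd)), 0, 10)`.
#'
#' @param fidelity Per-event fidelities in `[0, 1]`.
#' @param noise_sd Rating noise standard deviation on the 0-10 scale.
#' @param seed Optional seed.
#' @param participant_id,narrative_id Labels for the table.
#' @return data.frame with columns `participant_id`, `narrative_id`,
#'   `event_index` (1-based), `gist`.
#' @export
simulate_rater_scores <- function(fidelity, noise_sd = 0, seed = NULL,
                                  participant_id = "sim",
                                  narrative_id = "synthetic") {
  if (any(fidelity < 0) || any(fidelity > 1)) {
    es_error("fidelities must lie in [0, 1]", "eventseg_invalid_input")
  }
  with_seed(seed, {
    gist <- pmin(pmax(round(10 * fidelity +
                              stats::rnorm(length(fidelity), 0, noise_sd)), 0), 10)
    data.frame(participant_id = participant_id, narrative_id = narrative_id,
               event_index = seq_along(fidelity), gist = as.integer(gist),
               stringsAsFactors = FALSE)
  })
}

#' Default mapping from temperature to segmenter noise
#'
#' Temperature 0 reproduces the latent boundaries exactly; higher
#' temperatures degrade the hit rate, add positional jitter, and raise the
#' false-alarm rate (so higher temperatures also produce *more* boundaries).
#'
#' @return Named list of `eventseg_segmenter_model`s keyed by temperature.
#' @export
default_temperature_map <- function() {
  list(`0` = segmenter_model(1, 0, 0),
       `0.5` = segmenter_model(0.9, 1, 2),
       `1` = segmenter_model(0.8, 2, 6))
}

#' Deterministic mock generation client
#'
#' Stands in for a hosted chat-completion model: returns a word-for-word
#' copy of the narrative with newlines inserted at boundary positions drawn
#' from [simulate_rater()] under the segmenter model mapped to the requested
#' temperature. With a seed, the full multi-instance output is reproducible;
#' instance outputs differ from each other unless the mapped model is
#' noiseless.
#'
#' @param narr The narrative the client will be prompted with.
#' @param gt Ground-truth boundary indices for that narrative.
#' @param temperature_map Named list of segmenter models keyed by the
#'   *requested* temperature value (see [default_temperature_map()]).
#' @param seed Optional base seed; each (temperature, instance) pair derives
#'   its own stream from it.
#' @return A generation client
#'   `function(prompt, temperature, max_tokens, instance_index)`.
#' @export
mock_generation_client <- function(narr, gt,
                                   temperature_map = default_temperature_map(),
                                   seed = NULL) {
  stopifnot(inherits(narr, "eventseg_narrative"))
  gt <- validate_boundaries(gt, narr$word_count)
  function(prompt, temperature, max_tokens, instance_index) {
    key <- as.character(temperature)
    model <- temperature_map[[key]]
    if (is.null(model)) {
      es_error(sprintf("no segmenter model mapped to temperature %s", key),
               "eventseg_invalid_input")
    }
    if (!is.null(seed)) {
      model$seed <- (seed %% 1000003L) * 2000L + instance_index * 11L +
        as.integer(round(as.numeric(temperature) * 10))
    }
    resp <- simulate_rater(gt, model, narr$word_count)
    sep <- rep(" ", narr$word_count)
    if (length(resp$boundaries)) sep[resp$boundaries] <- "\n"
    paste0(narr$tokens, c(sep[-narr$word_count], ""), collapse = "")
  }
}

# compact pseudo-word vocabulary for structural filler text
synthetic_vocabulary <- function() {
  c("tora", "melik", "sunda", "pire", "vosk", "ander", "lumo", "chaparral",
    "quill", "brint", "oseta", "karn", "welv", "diro", "fenna", "gorse",
    "halin", "ipso", "jarel", "kresh", "lindo", "morva", "nylat", "ovrin",
    "palt", "quorn", "reska", "solin", "trev", "ulmar", "vint", "wexo",
    "yarrow", "zelim", "arbel", "bruny", "cassa", "dovel", "erren", "frith")
}

#' Generate a synthetic narrative
#'
#' Structural filler text (pseudo-word sentences) with the length and
#' tokenization properties of a real narrative; no linguistic content is
#' modeled.
#'
#' @param word_count Number of words.
#' @param seed Optional seed.
#' @param id Narrative identifier.
#' @return An `eventseg_narrative`.
#' @export
synthetic_narrative <- function(word_count = 1500L, seed = NULL,
                                id = "synthetic") {
  with_seed(seed, {
    vocab <- synthetic_vocabulary()
    words <- sample(vocab, word_count, replace = TRUE)
    # sentence-final punctuation every 8-15 words
    i <- 0L
    while (i < word_count) {
      i <- i + sample(8:15, 1)
      if (i <= word_count) words[i] <- paste0(words[i], ".")
    }
    words[1] <- paste0(toupper(substr(words[1], 1, 1)), substring(words[1], 2))
    narrative(id, paste(words, collapse = " "))
  })
}

#' Simulate a full segmentation study
#'
#' Builds one synthetic narrative with latent normative boundaries, a human
#' cohort of noisy segmenters, and mock-LLM instance runs at each requested
#' temperature -- the study conditions under which the package's analyses
#' are validated.
#'
#' @param word_count Narrative length (default 1500 words).
#' @param n_boundaries Latent boundary count (default 13).
#' @param min_separation Minimum gap between latent boundaries (default 20).
#' @param n_humans Human cohort size (default 20).
#' @param n_instances Mock-LLM instances per temperature (default 20).
#' @param temperatures Temperatures to run (default 0, 0.5, 1).
#' @param human_model Segmenter model for humans (default hit rate 0.7,
#'   jitter 1 word, 2 false alarms per 1000 words).
#' @param temperature_map Temperature-to-noise mapping for the mock client.
#' @param seed Seed for the whole study.
#' @param narrative_id Identifier of the synthetic narrative.
#' @return List with `narrative`, `ground_truth`, `human_responses` (list of
#'   `eventseg_response`), and `llm_runs` (named by temperature,
#'   `eventseg_segmentation_run` each).
#' @export
simulate_segmentation_study <- function(word_count = 1500L,
                                        n_boundaries = 13L,
                                        min_separation = 20L,
                                        n_humans = 20L, n_instances = 20L,
                                        temperatures = c(0, 0.5, 1),
                                        human_model = segmenter_model(0.7, 1, 2),
                                        temperature_map = default_temperature_map(),
                                        seed = NULL,
                                        narrative_id = "synthetic") {
  seed <- if (is.null(seed)) sample.int(1e6, 1) else seed
  narr <- synthetic_narrative(word_count, seed = seed, id = narrative_id)
  gt <- simulate_ground_truth(word_count, n_boundaries, min_separation,
                              seed = seed + 1L)
  humans <- lapply(seq_len(n_humans), function(i) {
    hm <- human_model
    hm$seed <- seed + 100L + i
    simulate_rater(gt, hm, word_count,
                   rater_id = sprintf("human_%02d", i), source = "human",
                   condition = "human", narrative_id = narr$id)
  })
  client <- mock_generation_client(narr, gt, temperature_map, seed = seed)
  llm_runs <- lapply(temperatures, function(temp) {
    cfg <- model_config(temperature = temp, n_instances = n_instances,
                        seed = seed)
    run_instances(narr, cfg, client)
  })
  names(llm_runs) <- as.character(temperatures)
  list(narrative = narr, ground_truth = gt, human_responses = humans,
       llm_runs = llm_runs, seed = seed)
}
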