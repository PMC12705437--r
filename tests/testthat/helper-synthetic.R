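# Small fixture builders used across test files.

# cohort of word-level series from noisy segmenters around shared boundaries
make_cohort <- function(n_raters, word_count, gt, model, seed = 1,
                        narrative_id = "n1", source = "human") {
  lapply(seq_len(n_raters), function(i) {
    m <- model
    m$seed <- seed + i
    to_series(simulate_rater(gt, m, word_count,
                             rater_id = sprintf("r%02d", i), source = source,
                             narrative_id = narrative_id),
              word_count)
  })
}

# unit-normalized narrative embedding set built with the fixture embedder
make_narr_set <- function(n_events = 13, dim = 128, seed = 3, id = "n1") {
  vocab <- c("tora", "melik", "sunda", "pire", "vosk", "ander", "lumo",
             "quill", "brint", "oseta", "karn", "welv", "diro", "fenna")
  texts <- with_test_seed(seed, vapply(seq_len(n_events), function(i) {
    paste(sample(vocab, 12, replace = TRUE), collapse = " ")
  }, character(1)))
  s <- embed_segments(texts, fixture_embedder(dim = dim, seed = seed),
                      owner_id = id, narrative_id = id)
  s$vectors <- s$vectors / sqrt(rowSums(s$vectors^2))
  s
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# embedding set from explicit vectors
vec_set <- function(vectors, owner = "p", narr = "n1") {
  embedding_set(owner, narr, sprintf("<seg %d>", seq_len(nrow(vectors))),
                vectors)
}
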