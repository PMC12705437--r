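# Text embedding plumbing. Embedding models are injected via a contract:
# an embedder is any function(texts) -> numeric matrix with one row per
# text. The bundled fixture embedder (a seeded random projection of token
# hash counts) keeps every test and example deterministic and offline;
# production backends (sentence encoders, hosted embedding APIs) plug in
# through the same contract.

#' Construct an embedding set
#'
#' One owner's ordered event segments and their embedding vectors for one
#' narrative. Constant (zero-variance) vectors are permitted but flagged,
#' since rank correlations against them are undefined.
#'
#' @param owner_id Participant/narrative identifier owning the segments.
#' @param narrative_id Narrative the segments belong to.
#' @param segment_texts Ordered character vector of segment texts.
#' @param vectors Numeric matrix, `length(segment_texts)` rows.
#' @return Object of class `eventseg_embedding_set`; attribute
#'   `constant_rows` lists flagged rows (if any).
#' @export
embedding_set <- function(owner_id, narrative_id, segment_texts, vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != length(segment_texts)) {
    es_error("one embedding row per segment text required",
             "eventseg_invalid_input")
  }
  if (ncol(vectors) < 2L) {
    es_error("embedding dimension must be at least 2", "eventseg_invalid_input")
  }
  const <- which(apply(vectors, 1L, function(r) stats::var(r) == 0))
  obj <- structure(
    list(owner_id = owner_id, narrative_id = narrative_id,
         segment_texts = segment_texts, vectors = vectors,
         n_segments = nrow(vectors), dim = ncol(vectors)),
    class = "eventseg_embedding_set"
  )
  if (length(const)) {
    es_log(sprintf("embedding set %s: %d constant vector(s) flagged",
                   owner_id, length(const)))
    attr(obj, "constant_rows") <- const
  }
  obj
}

#' @export
print.eventseg_embedding_set <- function(x, ...) {
  cat(sprintf("<embedding set %s/%s: %d segments x %d dims>\n",
              x$owner_id, x$narrative_id, x$n_segments, x$dim))
  invisible(x)
}

# Deterministic token hash into [0, buckets)
hash_token <- function(token, buckets) {
  codes <- utf8ToInt(token)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% buckets
  as.integer(h)
}

#' Deterministic fixture embedder
#'
#' Returns an embedder function mapping texts to `dim`-dimensional unit
#' vectors via a seeded random projection of hashed token counts. Texts
#' sharing many tokens get correlated vectors, so the embedder preserves the
#' coarse lexical-overlap structure that recall scoring relies on, while
#' requiring no model downloads or network access. It is a test fixture, not
#' a semantic model: paraphrases with disjoint vocabulary are unrelated
#' under it.
#'
#' @param dim Embedding dimension (default 256).
#' @param seed Seed for the projection matrix (default 1).
#' @param buckets Number of hash buckets (default 4096).
#' @return `function(texts) -> matrix` with `length(texts)` rows.
#' @export
fixture_embedder <- function(dim = 256L, seed = 1L, buckets = 4096L) {
  projection <- with_seed(seed, matrix(stats::rnorm(buckets * dim), buckets, dim))
  function(texts) {
    out <- matrix(0, length(texts), dim)
    for (i in seq_along(texts)) {
      toks <- normalize_tokens(tokenize(texts[i]))
      toks <- toks[nzchar(toks)]
      if (length(toks) == 0L) {
        es_error("cannot embed a text with no alphanumeric tokens",
                 "eventseg_invalid_input")
      }
      idx <- vapply(toks, hash_token, integer(1), buckets = buckets) + 1L
      v <- colSums(projection[idx, , drop = FALSE])
      out[i, ] <- v / sqrt(sum(v^2))
    }
    out
  }
}

#' Embed event segment texts into an embedding set
#'
#' @param texts Ordered segment texts.
#' @param embedder An embedder function (e.g. from [fixture_embedder()]).
#' @param owner_id,narrative_id Labels for the resulting set.
#' @return An `eventseg_embedding_set`.
#' @export
embed_segments <- function(texts, embedder, owner_id, narrative_id) {
  embedding_set(owner_id, narrative_id, texts, embedder(texts))
}
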