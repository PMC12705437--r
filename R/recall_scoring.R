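# Embedding-based recall scoring. A recall transcript segmented into events
# is compared against the segmented narrative through a Spearman similarity
# matrix; the matrix is resized to a square (narrative-events x
# narrative-events) form, row maxima give event-level recall scores, and
# unrelated narratives give a chance baseline. Pairwise recall x recall
# matrices yield intersubject temporal agreement (diagonal vs. reverse
# diagonal).

#' Spearman rank correlation between two vectors
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#' Rank correlation is used instead of cosine similarity throughout because
#' it is less sensitive to outlying embedding dimensions.
#'
#' @param u,v Numeric vectors of equal length (at least 3), neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
rank_correlation <- function(u, v) {
  if (length(u) != length(v) || length(u) < 3L) {
    es_error("vectors must have equal length >= 3", "eventseg_invalid_input")
  }
  if (stats::var(u) == 0 || stats::var(v) == 0) {
    es_error("rank correlation undefined for a constant vector",
             "eventseg_undefined_correlation")
  }
  stats::cor(u, v, method = "spearman")
}

#' Narrative x recall semantic similarity matrix
#'
#' Cell `(i, j)` is the Spearman correlation between the embedding of
#' narrative segment `i` and recall segment `j`. Rows follow narrative event
#' order, columns recall order. Constant embedding vectors produce a row or
#' column of missing values and are flagged with a warning rather than
#' silently imputed.
#'
#' @param narr_set,recall_set `eventseg_embedding_set`s of equal dimension.
#' @return Numeric matrix of class `eventseg_similarity_matrix`.
#' @export
similarity_matrix <- function(narr_set, recall_set) {
  stopifnot(inherits(narr_set, "eventseg_embedding_set"),
            inherits(recall_set, "eventseg_embedding_set"))
  if (narr_set$dim != recall_set$dim) {
    es_error("embedding dimensions differ", "eventseg_invalid_input")
  }
  # rank within each vector, then Pearson across dimensions
  rank_rows <- function(m) apply(m, 1L, rank)      # dim x n_segments
  ra <- rank_rows(narr_set$vectors)
  rb <- rank_rows(recall_set$vectors)
  m <- suppressWarnings(stats::cor(ra, rb))
  const_a <- attr(narr_set, "constant_rows")
  const_b <- attr(recall_set, "constant_rows")
  if (length(const_a)) m[const_a, ] <- NA_real_
  if (length(const_b)) m[, const_b] <- NA_real_
  if (length(const_a) || length(const_b)) {
    warning("constant embedding vectors: corresponding rows/columns set to NA",
            call. = FALSE)
  }
  structure(m, class = c("eventseg_similarity_matrix", class(m)))
}

# Bilinear interpolation weights from nin source pixels to nout output
# pixels, pixel-center convention with edge clamping (no smoothing):
# source coordinate of output pixel i (0-based) is (i + 0.5) * nin/nout - 0.5.
bilinear_weights <- function(nin, nout) {
  W <- matrix(0, nout, nin)
  pos <- (seq_len(nout) - 0.5) * nin / nout - 0.5
  pos <- pmin(pmax(pos, 0), nin - 1)
  lo <- pmin(floor(pos), nin - 1)
  frac <- pos - lo
  hi <- pmin(lo + 1, nin - 1)
  for (i in seq_len(nout)) {
    W[i, lo[i] + 1L] <- W[i, lo[i] + 1L] + (1 - frac[i])
    W[i, hi[i] + 1L] <- W[i, hi[i] + 1L] + frac[i]
  }
  W
}

#' Resize a similarity matrix to square form
#'
#' Bilinear interpolation of the matrix viewed as an image onto an
#' `n x n` grid (pixel-center convention, edge clamping, no smoothing or
#' anti-aliasing), with output clamped to `[-1, 1]`. Resizing an `n x n`
#' matrix to `n x n` is the identity. This puts participants with different
#' recall event counts on the narrative's event grid so their matrices can
#' be averaged and scored uniformly.
#'
#' @param m Numeric matrix (narrative x recall similarities).
#' @param n Target size (number of narrative events), at least 2.
#' @return `n x n` matrix of class `eventseg_square_matrix`.
#' @export
resize_square <- function(m, n) {
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L) {
    es_error("cannot resize an empty matrix", "eventseg_invalid_input")
  }
  if (!is_whole(n) || n < 2L) {
    es_error("target size must be an integer >= 2", "eventseg_invalid_input")
  }
  n <- as.integer(n)
  Wr <- bilinear_weights(nrow(m), n)
  Wc <- bilinear_weights(ncol(m), n)
  out <- Wr %*% m %*% t(Wc)
  out <- pmin(pmax(out, -1), 1)
  structure(out, class = c("eventseg_square_matrix", "matrix", "array"))
}

#' Event-level and narrative-level recall scores from a square matrix
#'
#' The row maximum is the best-matching recalled event for each narrative
#' event (the event-specific recall score); their mean is the participant's
#' narrative recall score. Rows that are entirely missing are flagged and
#' excluded from the mean with a logged message.
#'
#' @param sq Square similarity matrix (from [resize_square()]).
#' @param participant_id,narrative_id,model_label Labels for the result.
#' @param score_type `"actual"` or `"baseline"`.
#' @return Object of class `eventseg_recall_scores` with fields `per_event`
#'   and `narrative_score`.
#' @export
event_recall_scores <- function(sq, participant_id = "", narrative_id = "",
                                model_label = "", score_type = "actual") {
  m <- unclass(sq)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  per_event <- apply(m, 1L, function(r) {
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  })
  if (anyNA(per_event)) {
    es_log(sprintf("%d narrative event(s) with no defined similarity excluded from mean",
                   sum(is.na(per_event))))
  }
  structure(
    list(participant_id = participant_id, narrative_id = narrative_id,
         model_label = model_label, per_event = per_event,
         narrative_score = mean(per_event, na.rm = TRUE),
         score_type = score_type),
    class = "eventseg_recall_scores"
  )
}

#' Score a recall against its narrative
#'
#' The full actual-score pipeline: similarity matrix, square resize to the
#' narrative's event count, row maxima, mean.
#'
#' @param narr_set Narrative embedding set.
#' @param recall_set Recall embedding set (same embedding dimension).
#' @param model_label Embedding model label stored on the scores.
#' @param score_type Stored score type (default `"actual"`).
#' @return An `eventseg_recall_scores`.
#' @export
score_recall <- function(narr_set, recall_set, model_label = "",
                         score_type = "actual") {
  sq <- resize_square(similarity_matrix(narr_set, recall_set),
                      narr_set$n_segments)
  event_recall_scores(sq, participant_id = recall_set$owner_id,
                      narrative_id = narr_set$narrative_id,
                      model_label = model_label, score_type = score_type)
}

#' Baseline (non-corresponding narrative) recall scores
#'
#' Runs the full actual-score pipeline of the recall against each unrelated
#' narrative and averages the resulting narrative scores: the chance floor
#' for embedding-based recall scores. Per-event scores are averaged across
#' the unrelated narratives when their event counts agree and omitted
#' otherwise (the narrative-level baseline is the quantity of interest).
#'
#' @param recall_set Recall embedding set.
#' @param other_narratives Non-empty list of embedding sets from unrelated
#'   narratives.
#' @param model_label Embedding model label.
#' @return An `eventseg_recall_scores` with `score_type = "baseline"`.
#' @export
baseline_scores <- function(recall_set, other_narratives, model_label = "") {
  if (length(other_narratives) == 0L) {
    es_error("need at least one unrelated narrative", "eventseg_invalid_input")
  }
  per <- lapply(other_narratives, function(nset) {
    score_recall(nset, recall_set, model_label, score_type = "baseline")
  })
  scores <- vapply(per, function(s) s$narrative_score, numeric(1))
  lens <- vapply(per, function(s) length(s$per_event), integer(1))
  per_event <- if (length(unique(lens)) == 1L) {
    rowMeans(do.call(cbind, lapply(per, `[[`, "per_event")), na.rm = TRUE)
  } else {
    NULL
  }
  structure(
    list(participant_id = recall_set$owner_id,
         narrative_id = recall_set$narrative_id, model_label = model_label,
         per_event = per_event, narrative_score = mean(scores),
         score_type = "baseline"),
    class = "eventseg_recall_scores"
  )
}

#' Intersubject recall agreement (temporal order)
#'
#' For each ordered pair of participants, the recall x recall similarity
#' matrix is resized to the narrative's event count; its main diagonal
#' measures recalling the narrative in the same order as the other
#' participant, the reverse diagonal recalling it in reverse order (the
#' control). Each participant's diagonal and reverse-diagonal means are
#' averaged over their N-1 pairings. Participants with fewer than two recall
#' segments are excluded with a logged message.
#'
#' @param recall_sets List of `eventseg_embedding_set`s for one narrative
#'   (at least two usable participants).
#' @param n_events Narrative event count used for resizing.
#' @return data.frame with columns `participant_id`, `diag_mean`,
#'   `antidiag_mean`, `n_pairs`.
#' @export
intersubject_agreement <- function(recall_sets, n_events) {
  usable <- vapply(recall_sets, function(s) s$n_segments >= 2L, logical(1))
  if (any(!usable)) {
    es_log(sprintf("%d participant(s) with < 2 recall segments excluded",
                   sum(!usable)))
  }
  sets <- recall_sets[usable]
  n <- length(sets)
  if (n < 2L) {
    es_error("need at least two usable participants", "eventseg_invalid_input")
  }
  diag_idx <- cbind(seq_len(n_events), seq_len(n_events))
  anti_idx <- cbind(seq_len(n_events), rev(seq_len(n_events)))
  dsum <- numeric(n); asum <- numeric(n); npair <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      sq <- resize_square(similarity_matrix(sets[[i]], sets[[j]]), n_events)
      dsum[i] <- dsum[i] + mean(sq[diag_idx], na.rm = TRUE)
      asum[i] <- asum[i] + mean(sq[anti_idx], na.rm = TRUE)
      npair[i] <- npair[i] + 1L
    }
  }
  data.frame(
    participant_id = vapply(sets, function(s) s$owner_id, character(1)),
    diag_mean = dsum / npair, antidiag_mean = asum / npair, n_pairs = npair,
    stringsAsFactors = FALSE)
}

#' Standardize scores within embedding-model groups
#'
#' z-transforms a score column within each group (sample standard deviation,
#' n - 1), so score magnitudes are comparable across embedding models.
#'
#' @param scores data.frame of scores.
#' @param value Name of the numeric score column (default `"score"`).
#' @param group Name of the grouping column (default `"model_label"`).
#' @return The data.frame with the score column standardized per group.
#' @export
zscore_by_group <- function(scores, value = "score", group = "model_label") {
  stopifnot(is.data.frame(scores), value %in% names(scores),
            group %in% names(scores))
  for (g in unique(scores[[group]])) {
    sel <- scores[[group]] == g
    x <- scores[[value]][sel]
    if (length(x) < 2L) {
      es_error(sprintf("group '%s' has fewer than two scores", g),
               "eventseg_invalid_input")
    }
    s <- stats::sd(x)
    if (s == 0) {
      es_error(sprintf("group '%s' has zero score variance", g),
               "eventseg_invalid_input")
    }
    scores[[value]][sel] <- (x - mean(x)) / s
  }
  scores
}
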