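# Narrative text handling: tokenization, the boundary coordinate frame,
# parsing "segmented copy" model output back into boundary indices, and
# readers/writers for segmentation response tables.
#
# Coordinate conventions used throughout the package:
#   * word indices are 0-based;
#   * a boundary value b in [1, word_count - 1] means "one event ends just
#     before token b" (the narrative onset and offset are not drawn lines);
#   * event spans are half-open [start, end) token ranges.

#' Tokenize narrative text into words
#'
#' Words are maximal runs of non-whitespace characters; punctuation stays
#' attached to its word. The result is stable under re-tokenization of the
#' space-joined output.
#'
#' @param text A single character string.
#' @return Character vector of word tokens.
#' @examples
#' tokenize("Run! Go  Hitler")
#' @export
tokenize <- function(text) {
  assert_scalar_string(text, "text")
  if (!nzchar(trimws(text))) {
    es_error("text is empty or whitespace-only", "eventseg_invalid_input")
  }
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  tokens[nzchar(tokens)]
}

#' Construct a narrative object
#'
#' A narrative is the immutable coordinate frame for all boundary analyses:
#' its tokens define the word indices that every segmentation response and
#' word-level series refers to.
#'
#' @param id Narrative identifier.
#' @param text Narrative text (UTF-8 plain text).
#' @return An object of class `eventseg_narrative` with fields `id`, `text`,
#'   `tokens` and `word_count`.
#' @export
narrative <- function(id, text) {
  assert_scalar_string(id, "id")
  tokens <- tokenize(text)
  if (length(tokens) < 2L) {
    es_error("a narrative needs at least two words", "eventseg_invalid_input")
  }
  structure(
    list(id = id, text = text, tokens = tokens,
         word_count = length(tokens)),
    class = "eventseg_narrative"
  )
}

#' @export
print.eventseg_narrative <- function(x, ...) {
  cat(sprintf("<narrative '%s': %d words>\n", x$id, x$word_count))
  invisible(x)
}

word_count_of <- function(x) {
  if (inherits(x, "eventseg_narrative")) return(x$word_count)
  if (is.numeric(x) && length(x) == 1L && is_whole(x) && x > 1) {
    return(as.integer(x))
  }
  es_error("expected a narrative or a word count", "eventseg_invalid_input")
}

validate_boundaries <- function(boundaries, word_count) {
  if (length(boundaries) == 0L) return(integer(0))
  if (!all(is_whole(boundaries))) {
    es_error("boundary indices must be integers", "eventseg_coordinate_error")
  }
  b <- as.integer(round(boundaries))
  if (anyDuplicated(b)) {
    es_error("duplicate boundary indices", "eventseg_coordinate_error")
  }
  if (any(b < 1L) || any(b > word_count - 1L)) {
    es_error(sprintf(
      "boundary indices must lie in [1, %d] (0-based; onset/offset are not boundaries)",
      word_count - 1L), "eventseg_coordinate_error")
  }
  sort(b)
}

#' Construct a segmentation response
#'
#' One rater's (human participant or LLM instance) set of event boundary
#' word indices for one narrative, under a labeled condition (for LLM
#' instances, the temperature).
#'
#' @param rater_id Rater identifier.
#' @param source `"human"` or `"llm"`.
#' @param condition Condition label, e.g. a temperature value as a string.
#' @param narrative_id Narrative identifier.
#' @param boundaries Integer vector of 0-based boundary word indices.
#' @param word_count Optional word count used to validate the indices.
#' @return An object of class `eventseg_response`.
#' @export
segmentation_response <- function(rater_id, source = c("human", "llm"),
                                  condition = "", narrative_id, boundaries,
                                  word_count = NULL) {
  assert_scalar_string(rater_id, "rater_id")
  assert_scalar_string(narrative_id, "narrative_id")
  source <- match.arg(source)
  if (is.null(boundaries)) boundaries <- integer(0)
  if (!is.null(word_count)) {
    boundaries <- validate_boundaries(boundaries, word_count_of(word_count))
  } else {
    if (length(boundaries) && !all(is_whole(boundaries))) {
      es_error("boundary indices must be integers", "eventseg_coordinate_error")
    }
    boundaries <- sort(unique(as.integer(round(boundaries))))
    if (any(boundaries < 1L)) {
      es_error("boundary indices must be >= 1", "eventseg_coordinate_error")
    }
  }
  structure(
    list(rater_id = rater_id, source = source,
         condition = as.character(condition),
         narrative_id = narrative_id, boundaries = boundaries),
    class = "eventseg_response"
  )
}

#' @export
print.eventseg_response <- function(x, ...) {
  cat(sprintf("<response %s/%s narrative=%s condition=%s: %d boundaries>\n",
              x$source, x$rater_id, x$narrative_id, x$condition,
              length(x$boundaries)))
  invisible(x)
}

#' Convert a boundary set into event spans
#'
#' Returns the half-open token spans induced by a boundary set: `k`
#' boundaries partition the narrative into `k + 1` events whose tokens
#' concatenate back to the narrative token sequence.
#'
#' @param narr A narrative (or a bare word count).
#' @param boundaries Sorted 0-based boundary indices in `[1, word_count - 1]`.
#' @return A data.frame with columns `start` (inclusive) and `end`
#'   (exclusive), of class `eventseg_segmented_text`.
#' @export
spans_from_boundaries <- function(narr, boundaries) {
  wc <- word_count_of(narr)
  b <- validate_boundaries(boundaries, wc)
  spans <- data.frame(start = c(0L, b), end = c(b, wc))
  structure(spans,
            narrative_id = if (inherits(narr, "eventseg_narrative")) narr$id else NA_character_,
            class = c("eventseg_segmented_text", "data.frame"))
}

#' Extract event segment texts
#'
#' @param narr A narrative.
#' @param boundaries 0-based boundary indices.
#' @return Character vector: one space-joined text per event span.
#' @export
segment_texts <- function(narr, boundaries) {
  spans <- spans_from_boundaries(narr, boundaries)
  vapply(seq_len(nrow(spans)), function(i) {
    paste(narr$tokens[(spans$start[i] + 1L):spans$end[i]], collapse = " ")
  }, character(1))
}

# --- token alignment -------------------------------------------------------

# Lowercase and strip non-alphanumeric characters; tokens that normalize to
# the empty string never count as matches.
normalize_tokens <- function(tokens) {
  gsub("[^[:alnum:]]", "", tolower(tokens))
}

# Global (Needleman-Wunsch) alignment of token vector `b` (copy) onto `a`
# (original) with unit match/mismatch/indel scores. Returns, for every copy
# token, the 0-based index of the original token it aligns to (NA for
# insertions), plus which original tokens were matched exactly.
# The row update uses a cummax trick so the fill is vectorized over columns.
nw_align_tokens <- function(a, b) {
  n <- length(a)
  m <- length(b)
  H <- matrix(0, n + 1L, m + 1L)
  H[1L, ] <- -(0:m)
  H[, 1L] <- -(0:n)
  for (i in seq_len(n)) {
    s <- ifelse(b == a[i] & nzchar(a[i]), 1, -1)
    diag_sc <- H[i, 1:m] + s
    up_sc <- H[i, 2:(m + 1L)] - 1
    A <- pmax(diag_sc, up_sc)
    # H[i+1, j+1] = max over k <= j of W[k] - j, with W[0] = H[i+1, 1]
    W <- c(H[i + 1L, 1L], A + seq_len(m))
    V <- cummax(W)
    H[i + 1L, 2:(m + 1L)] <- V[-1L] - seq_len(m)
  }
  map <- rep(NA_integer_, m)
  matched <- logical(n)
  i <- n; j <- m
  # Tie preference diag > up > left keeps the alignment as early as possible.
  while (i > 0L && j > 0L) {
    s <- if (a[i] == b[j] && nzchar(a[i])) 1 else -1
    if (H[i + 1L, j + 1L] == H[i, j] + s) {
      map[j] <- i - 1L
      matched[i] <- (s == 1)
      i <- i - 1L; j <- j - 1L
    } else if (H[i + 1L, j + 1L] == H[i, j + 1L] - 1) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(map = map, matched = matched)
}

#' Parse a segmented word-for-word copy into boundary indices
#'
#' Language models are asked to copy a narrative word-for-word and start a
#' new line wherever one event ends. This maps each newline in the copy back
#' to a boundary index in the *original* narrative's word coordinates. For a
#' byte-identical copy the mapping is positional; otherwise normalized
#' tokens (lowercased, punctuation-stripped) are globally aligned and each
#' newline inherits the original index aligned to the copy token that
#' follows it. Newlines whose following token fails to align, or that fall
#' before the first word, are dropped with a logged message.
#'
#' @param narr A narrative.
#' @param copy_text The model's segmented copy.
#' @param min_fidelity Minimum fraction of original tokens that must be
#'   matched by the copy; below this the response is rejected as a degraded
#'   copy (error of class `eventseg_degraded_copy`).
#' @param rater_id,source,condition Labels stored on the response.
#' @return An `eventseg_response`; attribute `fidelity` records the token
#'   match fraction and attribute `no_boundaries` flags copies without any
#'   newline.
#' @export
parse_segmented_copy <- function(narr, copy_text, min_fidelity = 0.95,
                                 rater_id = "rater", source = "llm",
                                 condition = "") {
  stopifnot(inherits(narr, "eventseg_narrative"))
  assert_scalar_string(copy_text, "copy_text")
  if (!nzchar(trimws(copy_text))) {
    es_error("copy_text is empty", "eventseg_invalid_input")
  }
  lines <- strsplit(copy_text, "\n", fixed = TRUE)[[1L]]
  line_tokens <- lapply(lines, function(l) {
    if (nzchar(trimws(l))) tokenize(l) else character(0)
  })
  n_tok <- vapply(line_tokens, length, integer(1))
  copy_tokens <- unlist(line_tokens, use.names = FALSE)
  if (length(copy_tokens) == 0L) {
    es_error("copy_text contains no words", "eventseg_invalid_input")
  }
  # 0-based copy-token index that each newline precedes (first line has none)
  newline_pos <- unique(cumsum(n_tok)[-length(n_tok)])
  newline_pos <- newline_pos[newline_pos < length(copy_tokens)]

  norm_orig <- normalize_tokens(narr$tokens)
  norm_copy <- normalize_tokens(copy_tokens)
  if (length(norm_orig) == length(norm_copy) &&
      all(norm_orig == norm_copy)) {
    map <- seq_along(norm_copy) - 1L
    fidelity <- 1
  } else {
    aln <- nw_align_tokens(norm_orig, norm_copy)
    map <- aln$map
    fidelity <- mean(aln$matched)
  }
  if (fidelity < min_fidelity) {
    es_error(sprintf(
      "degraded copy: token fidelity %.3f below minimum %.3f (rater %s)",
      fidelity, min_fidelity, rater_id),
      "eventseg_degraded_copy", fidelity = fidelity)
  }

  boundaries <- integer(0)
  for (t in newline_pos) {
    idx <- map[t + 1L]           # original index aligned to following token
    if (is.na(idx)) {
      es_log(sprintf("dropped newline before unaligned copy token %d (rater %s)",
                     t, rater_id))
    } else if (idx == 0L) {
      es_log(sprintf("dropped newline at narrative onset (rater %s)", rater_id))
    } else {
      boundaries <- c(boundaries, idx)
    }
  }
  boundaries <- sort(unique(boundaries))
  resp <- segmentation_response(rater_id, source, condition, narr$id,
                                boundaries, word_count = narr$word_count)
  attr(resp, "fidelity") <- fidelity
  if (length(boundaries) == 0L) {
    es_log(sprintf("no boundaries in copy from rater %s", rater_id))
    attr(resp, "no_boundaries") <- TRUE
  }
  resp
}

# --- response tables -------------------------------------------------------

response_table_columns <- c("rater_id", "source", "condition",
                            "narrative_id", "boundaries")

responses_to_table <- function(responses) {
  stopifnot(length(responses) > 0L)
  data.frame(
    rater_id = vapply(responses, `[[`, character(1), "rater_id"),
    source = vapply(responses, `[[`, character(1), "source"),
    condition = vapply(responses, `[[`, character(1), "condition"),
    narrative_id = vapply(responses, `[[`, character(1), "narrative_id"),
    boundaries = vapply(responses, function(r) {
      paste(r$boundaries, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

table_to_responses <- function(tab, path = "<table>") {
  missing_cols <- setdiff(response_table_columns, names(tab))
  if (length(missing_cols)) {
    es_error(sprintf("%s: missing column(s): %s", path,
                     paste(missing_cols, collapse = ", ")),
             "eventseg_parse_error")
  }
  lapply(seq_len(nrow(tab)), function(i) {
    raw <- as.character(tab$boundaries[i])
    b <- integer(0)
    if (!is.na(raw) && nzchar(trimws(raw))) {
      parts <- trimws(strsplit(raw, ";", fixed = TRUE)[[1L]])
      parts <- parts[nzchar(parts)]
      vals <- suppressWarnings(as.numeric(parts))
      if (anyNA(vals)) {
        es_error(sprintf("%s: row %d, column 'boundaries': non-numeric value",
                         path, i), "eventseg_parse_error")
      }
      if (!all(is_whole(vals))) {
        es_error(sprintf("%s: row %d, column 'boundaries': non-integer index",
                         path, i), "eventseg_parse_error")
      }
      if (any(grepl(".", parts, fixed = TRUE))) {
        warning(sprintf("%s: row %d: float-formatted boundary index coerced to integer",
                        path, i), call. = FALSE)
      }
      b <- as.integer(round(vals))
    }
    segmentation_response(as.character(tab$rater_id[i]),
                          as.character(tab$source[i]),
                          as.character(tab$condition[i]),
                          as.character(tab$narrative_id[i]), b)
  })
}

#' Write / read segmentation responses as CSV
#'
#' The on-disk schema is one row per response with columns `rater_id`,
#' `source`, `condition`, `narrative_id` and `boundaries` (semicolon-joined
#' 0-based integers). Writing then reading reproduces the responses exactly;
#' float-formatted indices such as `"3.0"` are accepted with a warning.
#'
#' @param responses List of `eventseg_response` objects.
#' @param path File path.
#' @return `read_responses` returns a list of `eventseg_response`.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses_to_table(responses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) {
    es_error(sprintf("file not found: %s", path), "eventseg_missing_file")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  table_to_responses(tab, path)
}

#' @rdname write_responses
#' @export
write_responses_json <- function(responses, path) {
  recs <- lapply(responses, function(r) {
    list(rater_id = r$rater_id, source = r$source, condition = r$condition,
         narrative_id = r$narrative_id, boundaries = r$boundaries)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses_json <- function(path) {
  if (!file.exists(path)) {
    es_error(sprintf("file not found: %s", path), "eventseg_missing_file")
  }
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    for (f in response_table_columns[1:4]) {
      if (is.null(r[[f]])) {
        es_error(sprintf("%s: missing field '%s'", path, f),
                 "eventseg_parse_error")
      }
    }
    segmentation_response(r$rater_id, r$source, r$condition, r$narrative_id,
                          unlist(r$boundaries))
  })
}
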