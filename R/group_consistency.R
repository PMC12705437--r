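# Between-group boundary consistency: how often the event boundaries of a
# "main" human group reappear in a comparison group (a second human group or
# a group of LLM instances), assessed by a split-group permutation scheme.

#' Proportion of matched boundaries between two boundary sets
#'
#' The number of main-group boundaries found in the comparison set, divided
#' by the size of the smaller set (groups rarely produce the same number of
#' events, so the denominator is the sample with the fewest). With
#' `tolerance = 0` this is `|A intersect B| / min(|A|, |B|)`; with a positive
#' tolerance, matching is greedy one-to-one in sorted order and each
#' comparison boundary is usable once.
#'
#' @param set_a,set_b Non-empty 0-based boundary index sets.
#' @param tolerance Maximum distance in words for a match.
#' @return Proportion in `[0, 1]`.
#' @export
match_proportion <- function(set_a, set_b, tolerance = 0) {
  if (length(set_a) == 0L || length(set_b) == 0L) {
    es_error("match proportion undefined for an empty boundary set",
             "eventseg_invalid_input")
  }
  a <- sort(unique(set_a))
  b <- sort(unique(set_b))
  if (tolerance == 0) {
    matched <- length(intersect(a, b))
  } else {
    used <- logical(length(b))
    matched <- 0L
    for (x in a) {
      ok <- which(!used & abs(b - x) <= tolerance)
      if (length(ok)) {
        used[ok[1L]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  matched / min(length(a), length(b))
}

#' Split-group permutation test of boundary consistency
#'
#' Per iteration (and for one narrative), the human raters are randomly
#' split into a main group and a comparison group of `group_size` each, and
#' `group_size` LLM instances are drawn from the LLM pool. Each group's
#' boundary profile is averaged and its peaks taken as the group's event
#' boundaries; the iteration then yields two paired proportions sharing the
#' same main-group draw: main vs. human comparison and main vs. LLM
#' comparison. Iterations where a group has no peaks are skipped for that
#' comparison with a logged message.
#'
#' RNG draw order per iteration (relevant for reproducing a run from its
#' seed): one permutation of the human indices (first `group_size` = main,
#' next `group_size` = comparison), then one draw of `group_size` LLM
#' indices.
#'
#' @param human_series List of `eventseg_series` from human raters (at least
#'   `2 * group_size`).
#' @param llm_series List of `eventseg_series` from LLM instances (at least
#'   `group_size`).
#' @param iterations Number of permutation iterations (default 100).
#' @param group_size Raters per group (default 10).
#' @param seed Optional seed; the iteration table is fully reproducible from it.
#' @param tolerance Matching window in words (default 0, exact).
#' @param condition Condition label copied into the output.
#' @return data.frame with columns `iteration`, `narrative_id`, `comparison`
#'   (`human_vs_human` / `human_vs_llm`), `condition`, `proportion`.
#' @export
split_permutation_consistency <- function(human_series, llm_series,
                                          iterations = 100L, group_size = 10L,
                                          seed = NULL, tolerance = 0,
                                          condition = "") {
  n_h <- length(human_series)
  n_l <- length(llm_series)
  if (n_h < 2L * group_size) {
    es_error(sprintf("need at least %d human series, got %d",
                     2L * group_size, n_h), "eventseg_invalid_input")
  }
  if (n_l < group_size) {
    es_error(sprintf("need at least %d llm series, got %d", group_size, n_l),
             "eventseg_invalid_input")
  }
  nid <- human_series[[1L]]$narrative_id
  rows <- vector("list", 2L * iterations)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      perm <- sample.int(n_h)
      main_idx <- perm[seq_len(group_size)]
      comp_idx <- perm[group_size + seq_len(group_size)]
      llm_idx <- sample.int(n_l, group_size)

      main_peaks <- suppressWarnings(
        find_peaks(group_profile(human_series[main_idx])))
      comp_peaks <- suppressWarnings(
        find_peaks(group_profile(human_series[comp_idx])))
      llm_peaks <- suppressWarnings(
        find_peaks(group_profile(llm_series[llm_idx])))

      if (length(main_peaks) == 0L) {
        es_log(sprintf("iteration %d skipped: main group has no peaks", it))
        next
      }
      if (length(comp_peaks)) {
        rows[[2L * it - 1L]] <- data.frame(
          iteration = it, narrative_id = nid, comparison = "human_vs_human",
          condition = condition,
          proportion = match_proportion(main_peaks, comp_peaks, tolerance),
          stringsAsFactors = FALSE)
      } else {
        es_log(sprintf("iteration %d: human comparison group has no peaks", it))
      }
      if (length(llm_peaks)) {
        rows[[2L * it]] <- data.frame(
          iteration = it, narrative_id = nid, comparison = "human_vs_llm",
          condition = condition,
          proportion = match_proportion(main_peaks, llm_peaks, tolerance),
          stringsAsFactors = FALSE)
      } else {
        es_log(sprintf("iteration %d: llm comparison group has no peaks", it))
      }
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(iteration = integer(0), narrative_id = character(0),
                      comparison = character(0), condition = character(0),
                      proportion = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
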