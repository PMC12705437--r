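# Word-level boundary series and the statistics computed from them:
# leave-one-out agreement indices, boundary-rate scaling, shared/distinct
# boundary classification against an LLM group, peak detection on group
# profiles, and normative-boundary extraction.

#' Convert a segmentation response into a binary word-level series
#'
#' Element `b + 1` (0-based index `b`) is 1 when an event boundary was
#' identified just prior to word `b`, and 0 otherwise. Index 0 (the
#' narrative onset) is always 0.
#'
#' @param response An `eventseg_response`.
#' @param word_count Narrative word count (or a narrative).
#' @return An object of class `eventseg_series` with fields `narrative_id`,
#'   `rater_id` and `values` (binary vector of length `word_count`).
#' @export
to_series <- function(response, word_count) {
  stopifnot(inherits(response, "eventseg_response"))
  wc <- word_count_of(word_count)
  b <- validate_boundaries(response$boundaries, wc)
  values <- integer(wc)
  values[b + 1L] <- 1L
  structure(
    list(narrative_id = response$narrative_id, rater_id = response$rater_id,
         values = values),
    class = "eventseg_series"
  )
}

series_values <- function(x) {
  if (inherits(x, "eventseg_series")) return(x$values)
  if (inherits(x, "eventseg_profile")) return(x$values)
  if (is.numeric(x)) return(x)
  es_error("expected a word-level series, profile, or numeric vector",
           "eventseg_invalid_input")
}

# 0-based indices marked by a series (or any boundary carrier)
marked_indices <- function(x) {
  if (inherits(x, "eventseg_response")) return(x$boundaries)
  which(series_values(x) != 0) - 1L
}

#' Average word-level series across raters
#'
#' The group boundary profile: each element is the proportion of raters who
#' identified a boundary just prior to that word (the profile "amplitude").
#'
#' @param series_list Non-empty list of `eventseg_series` of equal length.
#' @param group_label Label stored on the profile.
#' @return An object of class `eventseg_profile` with fields `narrative_id`,
#'   `group_label`, `values` and `n_raters`.
#' @export
group_profile <- function(series_list, group_label = "") {
  if (length(series_list) == 0L) {
    es_error("empty series list", "eventseg_invalid_input")
  }
  mats <- lapply(series_list, series_values)
  lens <- vapply(mats, length, integer(1))
  if (length(unique(lens)) != 1L) {
    es_error("series lengths differ", "eventseg_coordinate_error")
  }
  values <- colMeans(do.call(rbind, mats))
  nid <- if (inherits(series_list[[1L]], "eventseg_series")) {
    series_list[[1L]]$narrative_id
  } else NA_character_
  structure(
    list(narrative_id = nid, group_label = group_label,
         values = values, n_raters = length(series_list)),
    class = "eventseg_profile"
  )
}

#' Segmentation agreement index
#'
#' Point-biserial correlation between one rater's binary word-level series
#' and a reference group profile. With a continuous reference the
#' point-biserial correlation reduces to the Pearson product-moment
#' correlation, which is what is computed. Leave-one-out referencing (the
#' profile of all *other* raters in the same group) is handled by
#' [agreement_indices()].
#'
#' @param target An `eventseg_series` (binary, non-constant).
#' @param reference An `eventseg_profile` or numeric vector (non-constant).
#' @return Correlation in `[-1, 1]`.
#' @export
agreement_index <- function(target, reference) {
  tv <- series_values(target)
  rv <- series_values(reference)
  if (length(tv) != length(rv)) {
    es_error("series and reference lengths differ", "eventseg_coordinate_error")
  }
  if (stats::var(tv) == 0) {
    es_error("target series is constant (no or all-position boundaries); agreement undefined",
             "eventseg_undefined_correlation")
  }
  if (stats::var(rv) == 0) {
    es_error("reference profile is constant; agreement undefined",
             "eventseg_undefined_correlation")
  }
  stats::cor(tv, rv)
}

#' Leave-one-out agreement indices for a cohort
#'
#' For each rater, correlates their series against the average series of all
#' other raters in the cohort. Raters whose correlation is undefined
#' (constant series, e.g. zero boundaries) are flagged and excluded from the
#' usable values with a logged message, not silently dropped.
#'
#' @param series_list List of `eventseg_series` from one group.
#' @param reference_series Optional list: when supplied, every target is
#'   correlated against the mean profile of this *other* group instead
#'   (no leave-one-out), as in human-to-LLM agreement.
#' @return data.frame with columns `rater_id`, `agreement`, `flagged`.
#' @export
agreement_indices <- function(series_list, reference_series = NULL) {
  n <- length(series_list)
  if (is.null(reference_series) && n < 2L) {
    es_error("need at least two raters for leave-one-out agreement",
             "eventseg_invalid_input")
  }
  out <- data.frame(
    rater_id = vapply(series_list, function(s) s$rater_id, character(1)),
    agreement = NA_real_, flagged = FALSE, stringsAsFactors = FALSE)
  ref_all <- if (!is.null(reference_series)) {
    group_profile(reference_series)
  }
  for (i in seq_len(n)) {
    ref <- if (is.null(reference_series)) {
      group_profile(series_list[-i])
    } else {
      ref_all
    }
    val <- tryCatch(agreement_index(series_list[[i]], ref),
                    eventseg_undefined_correlation = function(e) {
                      es_log(sprintf("rater %s excluded: %s",
                                     out$rater_id[i], conditionMessage(e)))
                      NA_real_
                    })
    out$agreement[i] <- val
    out$flagged[i] <- is.na(val)
  }
  out
}

#' Boundary count scaled per 1000 words
#'
#' @param n_boundaries Boundary count.
#' @param word_count Narrative word count.
#' @return `n_boundaries / word_count * 1000`.
#' @export
boundaries_per_1000 <- function(n_boundaries, word_count) {
  if (any(n_boundaries < 0) || any(word_count <= 0)) {
    es_error("counts must be non-negative and word_count positive",
             "eventseg_invalid_input")
  }
  n_boundaries / word_count * 1000
}

#' Classify human boundaries as shared with or distinct from an LLM group
#'
#' Every position with positive human-profile amplitude is labeled `shared`
#' when at least one LLM series marks a boundary at the same location
#' (within `tolerance` words; default exact), otherwise `distinct`.
#'
#' @param human_profile An `eventseg_profile` from the human group.
#' @param llm_series List of `eventseg_series` (or responses) from LLM
#'   instances, same word count.
#' @param tolerance Matching window in words (0 = exact position).
#' @return data.frame with columns `index` (0-based), `human_proportion`,
#'   `label`.
#' @export
classify_shared_distinct <- function(human_profile, llm_series, tolerance = 0) {
  hv <- series_values(human_profile)
  llm_marks <- sort(unique(unlist(lapply(llm_series, marked_indices))))
  idx <- which(hv > 0) - 1L
  label <- vapply(idx, function(b) {
    if (length(llm_marks) && any(abs(llm_marks - b) <= tolerance)) "shared" else "distinct"
  }, character(1))
  data.frame(index = idx, human_proportion = hv[idx + 1L], label = label,
             stringsAsFactors = FALSE)
}

#' Find peaks in a group boundary profile
#'
#' A peak is a position with positive amplitude that is a local maximum of
#' the profile; the series edges are treated as minus-infinity flanks, and a
#' plateau (a run of equal values exceeding both flanks) contributes exactly
#' one peak at its first index.
#'
#' @param profile An `eventseg_profile` or numeric vector.
#' @return Sorted 0-based integer indices; empty (with a warning) for an
#'   all-zero profile.
#' @export
find_peaks <- function(profile) {
  v <- series_values(profile)
  if (all(v == 0)) {
    warning("all-zero profile: no peaks", call. = FALSE)
    return(integer(0))
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1L], -Inf)
  is_peak <- r$values > 0 & r$values > left & r$values > right
  sort(starts[is_peak] - 1L)
}

#' Extract normative boundaries from a group profile
#'
#' The group's consensus boundary set: the `n` positions with the largest
#' profile amplitudes, where `n` is the mean per-rater boundary count
#' rounded half-to-even. Amplitude ties are broken toward the earlier index
#' and logged. If fewer than `n` positions have positive amplitude, all
#' positive positions are returned with a warning.
#'
#' @param profile An `eventseg_profile`.
#' @param counts_per_rater Integer vector of per-rater boundary counts from
#'   the same group.
#' @return Sorted 0-based integer indices.
#' @export
normative_boundaries <- function(profile, counts_per_rater) {
  v <- series_values(profile)
  n <- as.integer(round(mean(counts_per_rater)))
  pos <- which(v > 0) - 1L
  if (length(pos) < n) {
    warning(sprintf(
      "requested %d normative boundaries but only %d positions have positive amplitude",
      n, length(pos)), call. = FALSE)
    return(sort(pos))
  }
  if (n <= 0L) return(integer(0))
  amp <- v[pos + 1L]
  ord <- order(-amp, pos)
  chosen <- pos[ord[seq_len(n)]]
  cutoff <- amp[ord[n]]
  if (sum(amp == cutoff) > sum(amp[ord[seq_len(n)]] == cutoff)) {
    es_log(sprintf("amplitude tie at %.4f broken toward earlier indices", cutoff))
  }
  sort(chosen)
}
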