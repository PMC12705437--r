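# Reliability of the automated recall scores against human gist ratings:
# split-half consistency with a shuffled permutation null and Spearman-Brown
# correction, plus confidence-rating scaling and t statistics for the
# boundary-validation experiment.

#' Spearman-Brown split-half correction
#'
#' `2 * rho / (1 + rho)`: adjusts a split-half correlation for the halved
#' sample length. Strictly increasing on `(-1, 1]` and fixing 0 and 1.
#'
#' @param rho Split-half correlation, greater than -1.
#' @return Corrected reliability.
#' @export
spearman_brown <- function(rho) {
  if (any(!is.finite(rho)) || any(rho <= -1)) {
    es_error("spearman_brown requires rho > -1", "eventseg_domain_error")
  }
  2 * rho / (1 + rho)
}

#' Scale a boundary confidence rating to [-1, 1]
#'
#' Yes-responses ("this marking is a true event boundary") map to
#' `+confidence/10`, no-responses to `-confidence/10`, so -1 is high
#' confidence in a non-boundary, +1 high confidence in a boundary, and
#' values near 0 are low confidence either way.
#'
#' @param response Logical (or `"yes"`/`"no"`) vector.
#' @param confidence Integer ratings in 1..10.
#' @return Numeric vector in `[-1, 1]`.
#' @export
scale_confidence <- function(response, confidence) {
  if (is.character(response)) {
    if (!all(response %in% c("yes", "no"))) {
      es_error("response must be 'yes'/'no' or logical", "eventseg_invalid_input")
    }
    response <- response == "yes"
  }
  if (!all(is_whole(confidence)) || any(confidence < 1) || any(confidence > 10)) {
    es_error("confidence must be integers in [1, 10]", "eventseg_invalid_input")
  }
  ifelse(response, 1, -1) * confidence / 10
}

#' Split-half consistency between automated and human recall scores
#'
#' Per iteration, participants are divided randomly into two equal halves
#' (with an odd count, the first half takes the extra participant). In the
#' first half the Spearman correlation between concatenated automated and
#' human event-level scores is computed (an "actual" value); in the second
#' half the human scores are shuffled before correlating (a "null" value).
#' The one-tailed permutation p-value is the add-one probability that a null
#' value is at least the mean actual correlation, and the Spearman-Brown
#' correction of that mean gives the reported reliability.
#'
#' @param auto data.frame with columns `participant_id`, `narrative_id`,
#'   `event_index`, `score` (automated event-level recall scores).
#' @param human data.frame with columns `participant_id`, `narrative_id`,
#'   `event_index`, `gist` (0-10 ratings), keyed on exactly the same triples.
#' @param iterations Number of split iterations (default 10000).
#' @param seed Optional seed.
#' @param shuffle_unit `"all"` shuffles human scores across every triple in
#'   the null half (default); `"within_participant"` shuffles within each
#'   participant's triples.
#' @param model_label Label stored on the result.
#' @return Object of class `eventseg_reliability` with fields `rho_mean`,
#'   `rho_actual` (iteration vector), `rho_null` (iteration vector),
#'   `p_one_tailed`, `rho_sb`, `iterations`.
#' @export
split_half_consistency <- function(auto, human, iterations = 10000L,
                                   seed = NULL,
                                   shuffle_unit = c("all", "within_participant"),
                                   model_label = "") {
  shuffle_unit <- match.arg(shuffle_unit)
  keys <- c("participant_id", "narrative_id", "event_index")
  stopifnot(all(c(keys, "score") %in% names(auto)),
            all(c(keys, "gist") %in% names(human)))
  if (any(human$gist < 0) || any(human$gist > 10)) {
    es_error("gist ratings must lie in [0, 10]", "eventseg_invalid_input")
  }
  key_of <- function(d) paste(d$participant_id, d$narrative_id, d$event_index,
                              sep = "\r")
  ka <- key_of(auto); kh <- key_of(human)
  if (nrow(auto) != nrow(human) || !setequal(ka, kh) || anyDuplicated(ka)) {
    es_error("auto and human tables must be keyed on identical (participant, narrative, event) triples",
             "eventseg_invalid_input")
  }
  human <- human[match(ka, kh), , drop = FALSE]

  participants <- unique(auto$participant_id)
  P <- length(participants)
  if (P < 4L) {
    es_error("need at least four participants", "eventseg_invalid_input")
  }
  if (P %% 2L == 1L) {
    es_log("odd participant count: the first half takes the extra participant")
  }
  rows_of <- split(seq_len(nrow(auto)), auto$participant_id)
  h1_size <- ceiling(P / 2)

  actual <- numeric(iterations)
  null <- numeric(iterations)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      perm <- sample(participants)
      r1 <- unlist(rows_of[perm[seq_len(h1_size)]], use.names = FALSE)
      r2 <- unlist(rows_of[perm[(h1_size + 1L):P]], use.names = FALSE)
      actual[it] <- suppressWarnings(
        stats::cor(auto$score[r1], human$gist[r1], method = "spearman"))
      hg <- human$gist[r2]
      if (shuffle_unit == "all") {
        hg <- sample(hg)
      } else {
        pid2 <- auto$participant_id[r2]
        for (p in unique(pid2)) {
          sel <- pid2 == p
          hg[sel] <- sample(hg[sel])
        }
      }
      null[it] <- suppressWarnings(
        stats::cor(auto$score[r2], hg, method = "spearman"))
    }
  })
  n_bad <- sum(is.na(actual)) + sum(is.na(null))
  if (n_bad > 0L) {
    es_log(sprintf("%d undefined split correlations excluded", n_bad))
  }
  rho_mean <- mean(actual, na.rm = TRUE)
  null_ok <- null[!is.na(null)]
  p <- (sum(null_ok >= rho_mean) + 1) / (length(null_ok) + 1)
  structure(
    list(model_label = model_label, rho_mean = rho_mean,
         rho_actual = actual, rho_null = null, p_one_tailed = p,
         rho_sb = spearman_brown(rho_mean), iterations = iterations),
    class = "eventseg_reliability"
  )
}

#' @export
print.eventseg_reliability <- function(x, ...) {
  cat(sprintf("<split-half reliability%s: rho_mean = %.3f, rho_SB = %.3f, p = %.4g (%d iterations)>\n",
              if (nzchar(x$model_label)) paste0(" [", x$model_label, "]") else "",
              x$rho_mean, x$rho_sb, x$p_one_tailed, x$iterations))
  invisible(x)
}

#' Summary statistics for boundary confidence ratings
#'
#' Scales each rating to `[-1, 1]` (see [scale_confidence()]), averages per
#' participant within each marking type across narratives, then reports the
#' per-condition mean with a one-sample t statistic against zero and an
#' independent two-sample t statistic (pooled variance) between the boundary
#' and non-boundary conditions.
#'
#' @param ratings data.frame with columns `participant_id`, `narrative_id`,
#'   `marking_type` (`"boundary"`/`"non_boundary"`), `is_boundary_response`
#'   (logical or `"yes"`/`"no"`) and `confidence` (1-10).
#' @return List with `per_condition` (data.frame: marking_type, mean, t, df,
#'   p) and `between` (t, df, p for boundary vs non-boundary).
#' @export
boundary_rating_summary <- function(ratings) {
  req <- c("participant_id", "narrative_id", "marking_type",
           "is_boundary_response", "confidence")
  stopifnot(is.data.frame(ratings), all(req %in% names(ratings)))
  if (!all(ratings$marking_type %in% c("boundary", "non_boundary"))) {
    es_error("marking_type must be 'boundary' or 'non_boundary'",
             "eventseg_invalid_input")
  }
  ratings$scaled <- scale_confidence(ratings$is_boundary_response,
                                     ratings$confidence)
  per <- stats::aggregate(scaled ~ participant_id + marking_type,
                          data = ratings, FUN = mean)
  conds <- c("boundary", "non_boundary")
  rows <- lapply(conds, function(cond) {
    x <- per$scaled[per$marking_type == cond]
    if (length(x) < 2L) {
      es_error(sprintf("need at least two participants per condition (%s)", cond),
               "eventseg_invalid_input")
    }
    if (stats::sd(x) == 0) {
      es_log(sprintf("condition %s: zero variance, t statistic degenerate", cond))
      t_val <- if (mean(x) == 0) 0 else sign(mean(x)) * Inf
      out <- data.frame(marking_type = cond, mean = mean(x), t = t_val,
                        df = length(x) - 1, p = NA_real_, n = length(x),
                        stringsAsFactors = FALSE)
      return(out)
    }
    tt <- stats::t.test(x, mu = 0)
    data.frame(marking_type = cond, mean = mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n = length(x), stringsAsFactors = FALSE)
  })
  b <- per$scaled[per$marking_type == "boundary"]
  nb <- per$scaled[per$marking_type == "non_boundary"]
  between <- if (stats::sd(c(b - mean(b), nb - mean(nb))) == 0) {
    es_log("between-condition comparison degenerate: zero pooled variance")
    d <- mean(b) - mean(nb)
    data.frame(t = if (d == 0) 0 else sign(d) * Inf,
               df = length(b) + length(nb) - 2, p = NA_real_)
  } else {
    tt2 <- stats::t.test(b, nb, var.equal = TRUE)
    data.frame(t = unname(tt2$statistic), df = unname(tt2$parameter),
               p = tt2$p.value)
  }
  list(per_condition = do.call(rbind, rows), between = between)
}
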