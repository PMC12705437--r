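# Word-level series, agreement indices, shared/distinct boundaries, peaks,
# normative boundaries.

test_that("to_series places ones just after each boundary", {
  r <- function(b) segmentation_response("r", "human", "h", "n1", b)
  expect_identical(to_series(r(2L), 5)$values, c(0L, 0L, 1L, 0L, 0L))
  expect_identical(to_series(r(integer(0)), 4)$values, rep(0L, 4))
  expect_identical(to_series(r(c(1L, 4L)), 5)$values, c(0L, 1L, 0L, 0L, 1L))
  expect_error(to_series(r(9L), 5), class = "eventseg_coordinate_error")
})

test_that("group_profile averages element-wise and matches a column-mean oracle", {
  mk <- function(v, id) structure(list(narrative_id = "n1", rater_id = id,
                                       values = v), class = "eventseg_series")
  p <- group_profile(list(mk(c(0, 1, 0), "a"), mk(c(0, 1, 1), "b")))
  expect_equal(p$values, c(0, 1, 0.5))
  expect_identical(p$n_raters, 2L)
  single <- group_profile(list(mk(c(0, 1, 0), "a")))
  expect_equal(single$values, c(0, 1, 0))
  expect_error(group_profile(list()), class = "eventseg_invalid_input")

  set.seed(4)
  rows <- lapply(1:4, function(i) mk(rbinom(12, 1, 0.3), paste0("r", i)))
  expect_equal(group_profile(rows)$values,
               oracle_colmeans(lapply(rows, `[[`, "values")))
})

test_that("agreement_index is the Pearson correlation of series and profile", {
  mk <- function(v) structure(list(narrative_id = "n1", rater_id = "t",
                                   values = v), class = "eventseg_series")
  # frozen 4-point case, expected value from the textbook formula
  target <- c(0, 1, 0, 0)
  profile <- c(0, 1, 0.5, 0)
  expected <- oracle_pearson(target, profile)
  expect_equal(expected, 0.870, tolerance = 5e-4)
  expect_equal(agreement_index(mk(target), profile), expected,
               tolerance = 1e-14)

  # identical vectors correlate at 1
  expect_equal(agreement_index(mk(c(0, 1, 0, 1)), c(0, 1, 0, 1)), 1)
  # constant series are undefined
  expect_error(agreement_index(mk(c(0, 0, 0, 0)), profile),
               class = "eventseg_undefined_correlation")
  expect_error(agreement_index(mk(target), c(0.5, 0.5, 0.5, 0.5)),
               class = "eventseg_undefined_correlation")
})

test_that("agreement_index matches a brute-force Pearson oracle on random cohorts", {
  set.seed(17)
  for (rep in 1:200) {
    wc <- sample(5:100, 1)
    n <- sample(2:10, 1)
    series <- lapply(seq_len(n), function(i) {
      k <- sample(seq_len(wc - 1L), 1)
      v <- integer(wc)
      v[sample(2:wc, k)] <- 1L
      structure(list(narrative_id = "n1", rater_id = paste0("r", i),
                     values = v), class = "eventseg_series")
    })
    ref <- group_profile(series[-1])
    if (stats::var(series[[1]]$values) == 0 || stats::var(ref$values) == 0) next
    expect_lt(abs(agreement_index(series[[1]], ref) -
                    oracle_pearson(series[[1]]$values, ref$values)), 1e-12)
  }
})

test_that("leave-one-out cohorts of identical raters agree at exactly 1", {
  v <- integer(30); v[c(5, 12, 20)] <- 1L
  series <- lapply(1:8, function(i) {
    structure(list(narrative_id = "n1", rater_id = paste0("r", i), values = v),
              class = "eventseg_series")
  })
  ai <- agreement_indices(series)
  expect_equal(ai$agreement, rep(1, 8))
  expect_false(any(ai$flagged))
})

test_that("raters with constant series are flagged and excluded, not fatal", {
  v <- integer(20); v[c(4, 9)] <- 1L
  good <- lapply(1:3, function(i) {
    structure(list(narrative_id = "n1", rater_id = paste0("g", i), values = v),
              class = "eventseg_series")
  })
  empty <- structure(list(narrative_id = "n1", rater_id = "z",
                          values = integer(20)), class = "eventseg_series")
  ai <- suppressMessages(agreement_indices(c(good, list(empty))))
  expect_identical(ai$flagged, c(FALSE, FALSE, FALSE, TRUE))
  expect_true(all(!is.na(ai$agreement[1:3])))
})

test_that("boundary counts scale per 1000 words", {
  expect_equal(boundaries_per_1000(30, 1500), 20)
  expect_equal(boundaries_per_1000(0, 1500), 0)
  expect_equal(boundaries_per_1000(7, 400), 17.5)
  expect_error(boundaries_per_1000(-1, 100), class = "eventseg_invalid_input")
})

test_that("shared/distinct classification is exact-position by default", {
  prof <- structure(list(narrative_id = "n1", group_label = "h",
                         values = c(0, 0, 0.6, 0, 0, 0, 0, 0.1, 0, 0),
                         n_raters = 10L), class = "eventseg_profile")
  llm <- list(structure(list(narrative_id = "n1", rater_id = "i0",
                             values = c(0, 0, 1, 0, 0, 0, 0, 0, 1, 0)),
                        class = "eventseg_series"))
  tab <- classify_shared_distinct(prof, llm)
  expect_identical(tab$index, c(2L, 7L))
  expect_equal(tab$human_proportion, c(0.6, 0.1))
  # LLM mark at 8 does not match human 7: exact positions
  expect_identical(tab$label, c("shared", "distinct"))
  # tolerance window turns the near-miss into a match
  expect_identical(classify_shared_distinct(prof, llm, tolerance = 1)$label,
                   c("shared", "shared"))
  # partition property: shared + distinct = all positive-amplitude indices
  expect_identical(sort(tab$index), which(prof$values > 0) - 1L)
})

test_that("find_peaks detects local maxima with the plateau-first rule", {
  expect_identical(find_peaks(c(0, 0.2, 0.5, 0.2, 0)), 2L)
  expect_identical(find_peaks(c(0, 0.3, 0.3, 0.1, 0.4, 0)), c(1L, 4L))
  expect_warning(p <- find_peaks(c(0, 0, 0)), "no peaks")
  expect_identical(p, integer(0))
  # rising edge at the end counts (edges are -Inf flanks)
  expect_identical(find_peaks(c(0, 0.1, 0.4)), 2L)

  set.seed(23)
  for (rep in 1:100) {
    v <- round(stats::runif(sample(3:40, 1)) * 4) / 4
    got <- suppressWarnings(find_peaks(v))
    expect_identical(got, oracle_peaks(v))
  }
})

test_that("normative boundaries take the top-n amplitudes, ties to earlier index", {
  mkp <- function(v) structure(list(narrative_id = "n1", group_label = "g",
                                    values = v, n_raters = 10L),
                               class = "eventseg_profile")
  expect_identical(normative_boundaries(mkp(c(0, 0.6, 0.2, 0.9, 0)), c(2, 2)),
                   c(1L, 3L))
  expect_identical(normative_boundaries(mkp(c(0, 0.5, 0.5, 0)), c(1, 1)), 1L)
  # n = mean count rounded half to even
  expect_identical(length(normative_boundaries(
    mkp(c(0, rep(0.5, 15))), c(12, 13, 13, 14))), 13L)
  expect_identical(length(normative_boundaries(
    mkp(c(0, rep(0.5, 15))), c(12, 13))), 12L)
  # n above the number of positive positions: return all with a warning
  expect_warning(
    nb <- normative_boundaries(mkp(c(0, 0.3, 0, 0.2, 0)), c(5, 5)),
    "positive amplitude")
  expect_identical(nb, c(1L, 3L))
})

test_that("mean agreement rises with hit rate and falls with false alarms", {
  wc <- 400L
  gt <- simulate_ground_truth(wc, 8, 20, seed = 99)
  grid_mean <- function(hit, fa) {
    vals <- numeric(0)
    for (rep in 1:20) {
      cohort <- make_cohort(12, wc, gt, segmenter_model(hit, 0, fa),
                            seed = 5000 + rep * 37 + round(hit * 100) + fa)
      ai <- suppressMessages(agreement_indices(cohort))
      vals <- c(vals, ai$agreement[!ai$flagged])
    }
    mean(vals)
  }
  hits <- c(0.5, 0.7, 0.9)
  fas <- c(0, 3, 6)
  m <- outer(hits, fas, Vectorize(grid_mean))
  # dominance of means across the 3 x 3 grid
  expect_true(all(diff(m[, 1]) > 0) && all(diff(m[, 2]) > 0) &&
                all(diff(m[, 3]) > 0))
  expect_true(all(diff(m[1, ]) < 0) && all(diff(m[2, ]) < 0) &&
                all(diff(m[3, ]) < 0))
})
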