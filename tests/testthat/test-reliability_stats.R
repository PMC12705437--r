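# Spearman-Brown correction, split-half consistency, confidence scaling,
# boundary-rating t statistics.

test_that("spearman_brown fixes 0 and 1 and is strictly increasing", {
  expect_identical(spearman_brown(0), 0)
  expect_identical(spearman_brown(1), 1)
  expect_identical(spearman_brown(0.5), 2 / 3)
  expect_error(spearman_brown(-1), class = "eventseg_domain_error")
  rho <- seq(-0.99, 1, by = 0.01)
  expect_true(all(diff(spearman_brown(rho)) > 0))
})

test_that("confidence ratings scale to signed tenths", {
  expect_equal(scale_confidence(TRUE, 10), 1)
  expect_equal(scale_confidence(FALSE, 10), -1)
  expect_equal(scale_confidence(TRUE, 1), 0.1)
  expect_equal(scale_confidence(c("yes", "no"), c(5, 5)), c(0.5, -0.5))
  expect_error(scale_confidence(TRUE, 0), class = "eventseg_invalid_input")
  expect_error(scale_confidence(TRUE, 11), class = "eventseg_invalid_input")
})

make_scores <- function(P = 8, E = 3, f = function(x) x * 10, noise = 0,
                        seed = 1) {
  set.seed(seed)
  pid <- rep(sprintf("p%02d", seq_len(P)), each = E)
  auto <- data.frame(participant_id = pid, narrative_id = "n1",
                     event_index = rep(seq_len(E), P),
                     score = stats::runif(P * E))
  human <- data.frame(participant_id = pid, narrative_id = "n1",
                      event_index = rep(seq_len(E), P),
                      gist = pmin(pmax(f(auto$score) +
                                         stats::rnorm(P * E, 0, noise), 0), 10))
  list(auto = auto, human = human)
}

test_that("perfect monotone association gives rho 1 and the minimal p", {
  d <- make_scores(P = 8, E = 3)
  r <- split_half_consistency(d$auto, d$human, iterations = 200, seed = 2)
  expect_equal(r$rho_mean, 1)
  expect_equal(r$rho_sb, 1)
  expect_equal(r$p_one_tailed, 1 / 201)
  expect_length(r$rho_null, 200)
})

test_that("split-half p is in (0, 1], never exactly zero", {
  d <- make_scores(P = 6, E = 4, noise = 2, seed = 3)
  r <- split_half_consistency(d$auto, d$human, iterations = 300, seed = 4)
  expect_gt(r$p_one_tailed, 0)
  expect_lte(r$p_one_tailed, 1)
  expect_equal(r$rho_sb, 2 * r$rho_mean / (1 + r$rho_mean))
})

test_that("null distributions from different seeds agree (KS distance)", {
  d <- make_scores(P = 20, E = 13, noise = 3, seed = 5)
  r1 <- split_half_consistency(d$auto, d$human, iterations = 10000, seed = 11)
  r2 <- split_half_consistency(d$auto, d$human, iterations = 10000, seed = 12)
  ks <- suppressWarnings(stats::ks.test(r1$rho_null, r2$rho_null))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("noisy linear association matches the analytic attenuation oracle", {
  # auto ~ N(0,1), human = auto + N(0,1): Pearson rho = 1/sqrt(2); for
  # bivariate normal data the population Spearman is (6/pi) asin(rho/2)
  P <- 20; E <- 13
  set.seed(6)
  pid <- rep(sprintf("p%02d", seq_len(P)), each = E)
  x <- stats::rnorm(P * E)
  auto <- data.frame(participant_id = pid, narrative_id = "n1",
                     event_index = rep(seq_len(E), P), score = x)
  # the monotone map onto the 0-10 gist scale leaves all ranks unchanged
  human <- data.frame(participant_id = pid, narrative_id = "n1",
                      event_index = rep(seq_len(E), P),
                      gist = 10 * stats::pnorm((x + stats::rnorm(P * E)) /
                                                 sqrt(2)))
  r <- split_half_consistency(auto, human, iterations = 1000, seed = 7)
  rho_s_expected <- (6 / pi) * asin(1 / sqrt(2) / 2)
  expect_lt(abs(r$rho_mean - rho_s_expected), 0.08)
})

test_that("mismatched keys and tiny cohorts are rejected", {
  d <- make_scores(P = 4, E = 2)
  bad <- d$human
  bad$event_index[1] <- 99
  expect_error(split_half_consistency(d$auto, bad, iterations = 10),
               class = "eventseg_invalid_input")
  d3 <- make_scores(P = 3, E = 2)
  expect_error(split_half_consistency(d3$auto, d3$human, iterations = 10),
               class = "eventseg_invalid_input")
  # odd participant count: allowed, larger first half logged
  d5 <- make_scores(P = 5, E = 3)
  expect_message(split_half_consistency(d5$auto, d5$human, iterations = 10,
                                        seed = 1),
                 "extra participant")
})

test_that("within-participant shuffling is available as the null unit", {
  d <- make_scores(P = 8, E = 4, noise = 1, seed = 8)
  r <- split_half_consistency(d$auto, d$human, iterations = 200, seed = 9,
                              shuffle_unit = "within_participant")
  expect_length(r$rho_null, 200)
  expect_true(all(is.finite(r$rho_null)))
})

test_that("boundary rating summaries reproduce textbook t statistics", {
  # all-confident construction: means pin to +1 / -1
  tab <- expand.grid(participant_id = sprintf("p%d", 1:3),
                     narrative_id = c("n1", "n2"),
                     marking_type = c("boundary", "non_boundary"),
                     stringsAsFactors = FALSE)
  tab$is_boundary_response <- tab$marking_type == "boundary"
  tab$confidence <- 10
  s <- suppressMessages(boundary_rating_summary(tab))
  expect_equal(s$per_condition$mean[s$per_condition$marking_type == "boundary"], 1)
  expect_equal(s$per_condition$mean[s$per_condition$marking_type == "non_boundary"], -1)

  # symmetric ratings: one-sample t near 0
  tab2 <- data.frame(
    participant_id = rep(sprintf("p%d", 1:4), each = 2),
    narrative_id = "n1",
    marking_type = "boundary",
    is_boundary_response = rep(c(TRUE, FALSE), 4),
    confidence = 6)
  tab2b <- tab2
  tab2b$marking_type <- "non_boundary"
  s2 <- boundary_rating_summary(rbind(tab2, tab2b))
  expect_equal(s2$per_condition$t, c(0, 0))

  # 5-participant fixture against hand-coded t formulas
  set.seed(10)
  fix <- expand.grid(participant_id = sprintf("p%d", 1:5),
                     narrative_id = c("n1", "n2", "n3"),
                     marking_type = c("boundary", "non_boundary"),
                     stringsAsFactors = FALSE)
  fix$is_boundary_response <- ifelse(fix$marking_type == "boundary",
                                     stats::runif(nrow(fix)) < 0.8,
                                     stats::runif(nrow(fix)) < 0.3)
  fix$confidence <- sample(1:10, nrow(fix), replace = TRUE)
  s3 <- boundary_rating_summary(fix)
  per <- stats::aggregate(
    scaled ~ participant_id + marking_type,
    data = transform(fix, scaled = ifelse(is_boundary_response, 1, -1) *
                       confidence / 10),
    FUN = mean)
  b <- per$scaled[per$marking_type == "boundary"]
  nb <- per$scaled[per$marking_type == "non_boundary"]
  expect_equal(s3$per_condition$t[s3$per_condition$marking_type == "boundary"],
               oracle_t_one(b), tolerance = 1e-12)
  expect_equal(s3$between$t, oracle_t_two(b, nb), tolerance = 1e-12)
  expect_equal(s3$between$df, 8)

  # single participant in a condition is an error
  expect_error(boundary_rating_summary(fix[fix$participant_id == "p1", ]),
               class = "eventseg_invalid_input")
})
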