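# Analyze module: food-found classification, success histogram, the
# signal-variation statistic, onsets, milestones, and the comparisons.

test_that("found_food applies the 15-of-last-20 criterion exactly", {
  mk <- function(steps_on) {
    on <- c(rep(FALSE, 80), rep(TRUE, steps_on), rep(FALSE, 20 - steps_on))
    tibble::tibble(trial = 1L, step = 1:100, food_site = 1L,
                   sender_pos = 0, receiver_pos = 0, emitted = 0.5,
                   perceived = 0, food_sensor = 0L, on_food = on)
  }
  expect_false(found_food(mk(14))$found)
  expect_true(found_food(mk(15))$found)
  expect_true(found_food(mk(20))$found)
  expect_equal(found_food(mk(15))$p_trial, 0.15)
  # steps on food before step 81 do not count
  early <- mk(0); early$on_food[1:80] <- TRUE
  expect_false(found_food(early)$found)
  expect_equal(found_food(early)$p_trial, 0)
  expect_error(found_food(mk(10)[-c(5, 70), ]), "incomplete")
})

test_that("success_histogram tabulates 0..5 with shares summing to 1", {
  h <- success_histogram(c(0, 0, 5, 3, 3, 3))
  expect_equal(h$successes, 0:5)
  expect_equal(h$count, c(2, 0, 0, 3, 0, 1))
  expect_equal(sum(h$count), 6)
  expect_equal(sum(h$share), 1)
  expect_error(success_histogram(c(1, 6)))
})

test_that("signal_variation matches hand-computed oracles", {
  # identical signals across trials -> 0
  em <- matrix(0.5, nrow = 100, ncol = 5)
  expect_equal(as.numeric(signal_variation(synthetic_log(em))), 0)
  # one trial differs by a constant 1 from the four identical others:
  # ordered-pair sum per step = 2 * 4 * 1 = 8; scaled by 2/(5*4) -> 0.8
  em2 <- matrix(0, nrow = 100, ncol = 5); em2[, 3] <- 1
  expect_equal(as.numeric(signal_variation(synthetic_log(em2))), 0.8)
  # constant levels 0, .25, .5, .75, 1: mean unordered |diff| = 0.5,
  # statistic = 2 * 0.5 = 1
  em3 <- matrix(rep(c(0, 0.25, 0.5, 0.75, 1), each = 100), nrow = 100)
  expect_equal(as.numeric(signal_variation(synthetic_log(em3))), 1)
  # the ordered-pair definition equals twice the mean unordered pairwise
  # absolute difference (independent oracle on random data)
  set.seed(5)
  em4 <- matrix(runif(500), nrow = 100)
  oracle <- mean(apply(em4, 1, function(v) 2 * mean(dist(v))))
  expect_equal(as.numeric(signal_variation(synthetic_log(em4))), oracle,
               tolerance = 1e-12)
})

test_that("signal_variation restricts to found trials and handles < 2", {
  em <- matrix(rep(c(0, 0.25, 0.5, 0.75, 1), each = 100), nrow = 100)
  # only trials 1 and 5 found: levels 0 and 1, statistic = 2 * 1 = 2... the
  # unordered mean |0-1| = 1, doubled ordered form = 2/(2*1) * 2 = 1 * 2 = 2
  sv <- signal_variation(synthetic_log(em, found = c(TRUE, FALSE, FALSE,
                                                     FALSE, TRUE)))
  expect_equal(as.numeric(sv), 2)
  expect_equal(attr(sv, "n_trials"), 2)
  sv1 <- signal_variation(synthetic_log(em, found = c(TRUE, rep(FALSE, 4))))
  expect_true(is.na(sv1))
  expect_equal(attr(sv1, "n_trials"), 1)
})

test_that("onset_delay finds the first supra-threshold perception", {
  log <- synthetic_log(matrix(0.5, 100, 5))
  log$perceived[log$trial == 2 & log$step >= 13] <- 0.4
  log$perceived[log$trial == 4 & log$step == 99] <- 1e-7  # below threshold
  od <- onset_delay(log)
  expect_equal(od$onset[od$trial == 2], 13L)
  expect_true(is.na(od$onset[od$trial == 1]))
  expect_true(is.na(od$onset[od$trial == 4]))
  expect_equal(onset_delay(log, threshold = 5e-8)$onset[4], 99L)
})

test_that("milestone extraction scans histories correctly", {
  # synthetic history: onset spread of the best pair exceeds 1 from gen 7;
  # per-pair performance rises above 0.2 sustainably from gen 9
  gens <- 30; n <- 60
  perf <- matrix(0.1, gens, n)
  set.seed(2)
  perf[9:gens, ] <- matrix(0.25 + 0.05 * runif((gens - 8) * n),
                           nrow = gens - 8)
  spread_best <- c(rep(0, 6), rep(3, gens - 6))
  h <- structure(list(
    summary = tibble::tibble(generation = 1:gens,
                             onset_spread_best = spread_best,
                             onset_spread_median = rep(NA_real_, gens)),
    perf = perf), class = "evolution_history")
  expect_equal(first_onset_variation_generation(h), 7L)
  expect_equal(first_onset_variation_generation(h, tolerance = 5),
               NA_integer_)
  expect_equal(first_exceeds_threshold_generation(h), 9L)
  expect_equal(first_exceeds_threshold_generation(h, threshold = 0.5),
               NA_integer_)
  h2 <- h; h2$perf <- NULL
  expect_error(first_exceeds_threshold_generation(h2), "keep_pair_perf")
})

test_that("the sustained-crossing rule ignores isolated lucky generations", {
  gens <- 60; n <- 60
  set.seed(3)
  perf <- matrix(0.1, gens, n)
  # a single lucky generation at 5, then a real sustained crossing at 30
  perf[5, ] <- 0.3
  perf[30:gens, ] <- matrix(0.25 + 0.05 * runif((gens - 29) * n),
                            nrow = gens - 29)
  h <- structure(list(summary = tibble::tibble(generation = 1:gens),
                      perf = perf), class = "evolution_history")
  expect_equal(first_exceeds_threshold_generation(h, sustain = 1), 5L)
  expect_equal(first_exceeds_threshold_generation(h, sustain = 20), 30L)
  # a sustained run truncated by the end of the history does not count
  perf2 <- matrix(0.1, gens, n)
  perf2[55:gens, ] <- 0.3
  h2 <- structure(list(summary = tibble::tibble(generation = 1:gens),
                       perf = perf2), class = "evolution_history")
  expect_equal(first_exceeds_threshold_generation(h2, sustain = 20),
               NA_integer_)
})

test_that("compare_treatments reports the Mann-Whitney comparison", {
  set.seed(9)
  a <- runif(50, 0.3, 0.5)
  b <- runif(50, 0.1, 0.2)
  cmp <- compare_treatments(a, b)
  expect_lt(cmp$p_value, 1e-6)
  expect_equal(cmp$direction, 1)
  expect_equal(cmp$median_a, median(a))
  # agrees with stats::wilcox.test directly
  expect_equal(cmp$p_value,
               suppressWarnings(wilcox.test(a, b, exact = FALSE))$p.value)
  # symmetric samples give a large p
  expect_gt(compare_treatments(a, a + 0)$p_value, 0.9)
  expect_error(compare_treatments(1, 1:5), "two observations")
})

test_that("correlate_milestones matches cor.test and validates input", {
  x <- c(3, 7, 10, 15, 22, 30)
  y <- c(5, 9, 13, 14, 25, 33)
  cm <- correlate_milestones(x, y)
  ht <- cor.test(x, y)
  expect_equal(cm$estimate, unname(ht$estimate))
  expect_equal(cm$p_value, ht$p.value)
  expect_equal(cm$n, 6)
  # NA pairs are dropped
  expect_equal(correlate_milestones(c(x, NA), c(y, 1))$n, 6)
  expect_error(correlate_milestones(1:2, 2:3), "at least 3")
  expect_error(correlate_milestones(rep(1, 5), 1:5), "zero variance")
})

test_that("population_success_counts stays within 0..5", {
  cfg <- evolution_config(generations = 1, n_pairs = 8, tournament_size = 4)
  pop <- init_population(cfg, seed = 3)
  counts <- population_success_counts(pop, seed = 1)
  expect_length(counts, 8)
  expect_true(all(counts %in% 0:5))
  h <- success_histogram(counts)
  expect_equal(sum(h$count), 8)
})
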