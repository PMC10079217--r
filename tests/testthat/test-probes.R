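# Probe module: null-manipulation identities (a probe that removes nothing
# must reproduce the control bit-for-bit) and the population-level plumbing.

test_that("fixing the amplitude at a constant emitter's value is a no-op", {
  # the stationary fixture (all genes 0.5) emits exactly 0.5 every step, and
  # 0.5 is exactly representable, so the override must be bit-neutral
  s <- make_fixture_genome("sender", "stationary")
  pair <- random_pair(1)
  ctrl <- evaluate_pair(s, pair$receiver, 1:5)
  expect_true(all(ctrl$log$emitted == 0.5))
  pr <- probe_fixed_amplitude(s, pair$receiver, amplitude = 0.5)
  expect_identical(pr$log$receiver_pos, ctrl$log$receiver_pos)
  expect_identical(pr$log$perceived, ctrl$log$perceived)
  expect_identical(pr$trials$p_trial, ctrl$trials$p_trial)
  expect_identical(pr$total, ctrl$total)
  # and a genuinely different constant changes the perceived signal
  pr2 <- probe_fixed_amplitude(s, pair$receiver, amplitude = 0.2)
  expect_false(identical(pr2$log$perceived, ctrl$log$perceived))
  expect_error(probe_fixed_amplitude(s, pair$receiver, amplitude = 1.3),
               "\\[0, 1\\]")
})

test_that("duration-locking a sender that never re-enters the nest is a no-op", {
  s <- make_fixture_genome("sender", "stationary")   # never leaves the nest
  pair <- random_pair(2)
  ctrl <- evaluate_pair(s, pair$receiver, 1:5)
  pr <- probe_duration_lock(s, pair$receiver, 1:5)
  expect_identical(pr$log$sender_pos, ctrl$log$sender_pos)
  expect_identical(pr$log$receiver_pos, ctrl$log$receiver_pos)
  expect_identical(pr$total, ctrl$total)
})

test_that("duration lock freezes the sender at its first nest re-entry", {
  # a full-speed ccw sender laps the circle every 18 steps: it leaves the
  # nest and re-enters on the way around; after that its position must be
  # constant for the rest of the trial
  s <- make_fixture_genome("sender", "constant_full_speed_ccw")
  pair <- random_pair(3)
  ctrl <- run_trial(s, pair$receiver, 1)
  pr <- probe_duration_lock(s, pair$receiver, c(1, 2, 3, 4, 5))
  locked <- pr$log[pr$log$trial == 1, ]
  w <- world_spec()
  outside <- !in_arc(ctrl$sender_pos, w$nest)
  reentry <- which(outside[-100] & in_arc(ctrl$sender_pos[-1], w$nest))[1] + 1
  expect_false(is.na(reentry))
  # identical up to the re-entry step, frozen afterwards
  expect_identical(locked$sender_pos[1:reentry], ctrl$sender_pos[1:reentry])
  expect_true(all(locked$sender_pos[reentry:100] ==
                    locked$sender_pos[reentry]))
  expect_false(all(ctrl$sender_pos[reentry:100] ==
                     ctrl$sender_pos[reentry]))
})

test_that("mean-amplitude replay of a constant emitter is a no-op", {
  # constant emission of exactly 0.5 in every trial: the per-step trial mean
  # is exactly the emitted value, so the replayed receiver must match
  s <- make_fixture_genome("sender", "stationary")
  pair <- random_pair(4)
  ctrl <- evaluate_pair(s, pair$receiver, 1:5)
  pr <- probe_mean_amplitude_replay(ctrl$log, pair$receiver)
  expect_identical(pr$log$receiver_pos, ctrl$log$receiver_pos)
  expect_identical(pr$log$perceived, ctrl$log$perceived)
  expect_identical(pr$trials$p_trial, ctrl$trials$p_trial)
  expect_identical(pr$total, ctrl$total)
  expect_error(probe_mean_amplitude_replay(ctrl$log[ctrl$log$trial == 1, ],
                                           pair$receiver), "several trials")
})

test_that("onset-shift of a pair with identical onsets is a zero-shift no-op", {
  # constant emitter, stationary sender: both agents start in the nest, so
  # the signal is perceived at step 1 in every trial and the shift is 0
  s <- make_fixture_genome("sender", "constant_amplitude", amplitude = 0.6)
  pair <- random_pair(5)
  ctrl <- evaluate_pair(s, pair$receiver, 1:5)
  expect_true(all(ctrl$trials$onset == 1L))
  pr <- probe_onset_shift(ctrl$log, pair$receiver)
  expect_true(pr$applicable)
  expect_equal(pr$shift, 0L)
  expect_identical(pr$log$receiver_pos, ctrl$log$receiver_pos)
  expect_identical(pr$total, ctrl$total)
})

test_that("onset-shift delays the available signal by the computed shift", {
  # hand-build a control log whose perceived onsets are 11 and 21:
  # mean |pairwise difference| = 10, so the probe shifts by 10 steps
  em <- matrix(0.6, 100, 2)
  log <- synthetic_log(em)
  log$perceived[log$trial == 1 & log$step >= 11] <- 0.6
  log$perceived[log$trial == 2 & log$step >= 21] <- 0.6
  r <- make_fixture_genome("receiver", "stationary")
  pr <- probe_onset_shift(log, r)
  expect_equal(pr$shift, 10L)
  # the synthetic sender sits at 0 (in nest), the stationary receiver too:
  # the replayed perceived signal is the emitted one delayed by 10 steps
  perceived1 <- pr$log$perceived[pr$log$trial == 1]
  expect_equal(perceived1, c(rep(0, 10), rep(0.6, 90)))
})

test_that("onset-shift is inapplicable without two perceived onsets", {
  pair <- random_pair(6)
  ctrl <- evaluate_pair(pair$sender, pair$receiver, 1:5, "no_communication")
  expect_true(all(ctrl$log$perceived == 0))
  pr <- probe_onset_shift(ctrl$log, pair$receiver)
  expect_false(pr$applicable)
  expect_true(is.na(pr$total))
})

test_that("probe_population returns paired totals for every pair", {
  set.seed(31)
  pop <- structure(list(senders = matrix(runif(3 * 77), 3),
                        receivers = matrix(runif(3 * 70), 3)),
                   class = "population")
  for (probe in c("fixed_amplitude", "duration_lock",
                  "mean_amplitude_replay", "onset_shift")) {
    tbl <- probe_population(pop, probe, seed = 2)
    expect_equal(nrow(tbl), 3)
    expect_named(tbl, c("pair", "control", "probe", "applicable"))
    expect_true(all(tbl$control >= 0 & tbl$control <= 1))
    expect_true(all(is.na(tbl$probe) | (tbl$probe >= 0 & tbl$probe <= 1)))
    expect_true(all(tbl$applicable | is.na(tbl$probe)))
  }
  # probes are deterministic given the seed
  t1 <- probe_population(pop, "fixed_amplitude", seed = 2)
  t2 <- probe_population(pop, "fixed_amplitude", seed = 2)
  expect_identical(t1, t2)
})

test_that("probe_significance flags a clear decrease and only a decrease", {
  set.seed(12)
  ctrl <- runif(40, 0.5, 0.7)
  tbl_down <- tibble::tibble(pair = 1:40, control = ctrl,
                             probe = ctrl - 0.3, applicable = TRUE)
  sig <- probe_significance(tbl_down)
  expect_true(sig$decreased)
  expect_lt(sig$p_value, 0.01)
  tbl_up <- tibble::tibble(pair = 1:40, control = ctrl, probe = ctrl + 0.2,
                           applicable = TRUE)
  expect_false(probe_significance(tbl_up)$decreased)
  tbl_null <- tibble::tibble(pair = 1:40, control = ctrl, probe = ctrl,
                             applicable = TRUE)
  expect_false(probe_significance(tbl_null)$decreased)
  # inapplicable rows are dropped from the comparison
  tbl_mix <- rbind(tbl_down,
                   tibble::tibble(pair = 41, control = 0.6, probe = NA,
                                  applicable = FALSE))
  expect_equal(probe_significance(tbl_mix)$n, 40)
})
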