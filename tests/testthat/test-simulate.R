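# Simulate module: trial mechanics, treatments, pair evaluation, and the
# fast-path vs naive-reference oracle equivalence.

test_that("fast C++ path matches the naive R reference bit-for-bit", {
  cols <- c("sender_pos", "receiver_pos", "emitted", "perceived",
            "food_sensor", "on_food")
  for (seed in 1:5) {
    pair <- random_pair(seed)
    site <- (seed %% 5) + 1
    for (tr in treatments()) {
      fast <- run_trial(pair$sender, pair$receiver, site, tr,
                        engine = "cpp")
      ref <- run_trial(pair$sender, pair$receiver, site, tr,
                       engine = "reference")
      for (cl in cols) {
        expect_lt(max(abs(as.numeric(fast[[cl]]) - as.numeric(ref[[cl]]))),
                  1e-12)
      }
    }
  }
  # and under the non-default numerical switches
  pair <- random_pair(99)
  opts <- sim_options(input_mode = "integrate", tau_form = "reciprocal")
  fast <- run_trial(pair$sender, pair$receiver, 3, options = opts)
  ref <- run_trial(pair$sender, pair$receiver, 3, options = opts,
                   engine = "reference")
  for (cl in cols) {
    expect_lt(max(abs(as.numeric(fast[[cl]]) - as.numeric(ref[[cl]]))),
              1e-12)
  }
})

test_that("trial logs have the documented shape and invariants", {
  pair <- random_pair(1)
  log <- run_trial(pair$sender, pair$receiver, 2)
  expect_s3_class(log, "tbl_df")
  expect_named(log, c("trial", "step", "food_site", "sender_pos",
                      "receiver_pos", "emitted", "perceived", "food_sensor",
                      "on_food"))
  expect_equal(nrow(log), 100)
  expect_equal(log$step, 1:100)
  expect_true(all(log$food_site == 2))
  # positions normalized; both agents start in the nest at 0
  expect_true(all(log$sender_pos >= -pi & log$sender_pos < pi))
  expect_equal(log$sender_pos[1], 0)
  expect_equal(log$receiver_pos[1], 0)
  # amplitudes are sigmoid outputs in (0, 1); perceived never exceeds emitted
  expect_true(all(log$emitted > 0 & log$emitted < 1))
  expect_true(all(log$perceived <= log$emitted))
  # perceived is exactly the nest-gated emission at the logged positions
  w <- world_spec()
  expect_equal(log$perceived,
               perceived_signal(log$sender_pos, log$receiver_pos,
                                log$emitted))
  # food sensor agrees with the world-module sensor at the logged positions
  expect_equal(log$food_sensor,
               food_sensor(log$sender_pos, 2))
  # on_food is receiver presence on the food-bearing site
  expect_equal(log$on_food, in_arc(log$receiver_pos, w$sites[[2]]))
  # agents never move faster than the speed limit
  expect_true(all(abs(normalize_angle(diff(log$sender_pos))) <=
                    w$max_speed + 1e-12))
  expect_true(all(abs(normalize_angle(diff(log$receiver_pos))) <=
                    w$max_speed + 1e-12))
})

test_that("a parked receiver scores exactly 0.2 in its trial", {
  s <- make_fixture_genome("sender", "stationary")
  for (site in 1:5) {
    log <- run_trial(s, parked_receiver(site), site)
    perf <- trial_performance(log)
    expect_equal(perf$p_trial, 0.2)
    expect_equal(perf$steps_on_food, 20)
  }
})

test_that("per-site parked receivers compose to the documented bounds", {
  # a receiver parked on site k earns 0.2 in the trial with food at k and
  # 0 in the others, so its five-trial total is exactly 0.2
  s <- make_fixture_genome("sender", "stationary")
  pp <- evaluate_pair(s, parked_receiver(3), food_order = 1:5)
  expect_equal(pp$total, 0.2)
  expect_equal(pp$trials$p_trial, c(0, 0, 0.2, 0, 0))
  # summing the five per-site maxima gives the absolute ceiling 1.0
  totals <- vapply(1:5, function(k) {
    evaluate_pair(s, parked_receiver(k), food_order = 1:5)$trials$p_trial[k]
  }, numeric(1))
  expect_equal(sum(totals), 1.0)
})

test_that("evaluate_pair validates the food order and sums the trials", {
  pair <- random_pair(3)
  expect_error(evaluate_pair(pair$sender, pair$receiver, c(1, 1, 2, 3, 4)),
               "permutation")
  expect_error(evaluate_pair(pair$sender, pair$receiver, 1:4), "permutation")
  pp <- evaluate_pair(pair$sender, pair$receiver, c(3, 1, 5, 2, 4))
  expect_equal(pp$trials$food_site, c(3L, 1L, 5L, 2L, 4L))
  expect_equal(pp$total, sum(pp$trials$p_trial))
  expect_equal(pp$total, sum(trial_performance(pp$log)$p_trial))
  expect_true(all(pp$trials$p_trial >= 0 & pp$trials$p_trial <= 0.2))
})

test_that("networks are reset between trials", {
  pair <- random_pair(4)
  pp <- evaluate_pair(pair$sender, pair$receiver, 1:5)
  single <- run_trial(pair$sender, pair$receiver, 4)
  merged <- pp$log[pp$log$trial == 4, ]
  expect_equal(merged$sender_pos, single$sender_pos)
  expect_equal(merged$emitted, single$emitted)
})

test_that("no-communication treatment zeroes perception and decouples roles", {
  pair <- random_pair(5)
  log <- run_trial(pair$sender, pair$receiver, 2, "no_communication")
  expect_true(all(log$perceived == 0))
  # the receiver's trajectory is invariant to the sender genome
  other <- random_pair(6)
  log2 <- run_trial(other$sender, pair$receiver, 2, "no_communication")
  expect_identical(log$receiver_pos, log2$receiver_pos)
  expect_identical(log$on_food, log2$on_food)
  # the sender still behaves normally (emits, senses food)
  expect_true(all(log$emitted > 0))
})

test_that("constrained senders march counterclockwise at full speed", {
  pair <- random_pair(7)
  log <- run_trial(pair$sender, pair$receiver, 3, "constrained_sender")
  w <- world_spec()
  expect_equal(log$sender_pos, normalize_angle(w$max_speed * (0:99)),
               tolerance = 1e-12)
  # emission stays network-controlled (non-constant in general)
  expect_gt(sd(log$emitted), 0)
  # identical sender trajectory across trials -> the perceived-signal gate
  # opens on the same schedule whenever the receiver is in the nest
  pp <- evaluate_pair(pair$sender, pair$receiver, 1:5, "constrained_sender")
  pos_by_trial <- matrix(pp$log$sender_pos, nrow = 100)
  expect_equal(pos_by_trial[, 1], pos_by_trial[, 5])
})

test_that("evaluate_population agrees with per-pair evaluation", {
  set.seed(11)
  n <- 4
  senders <- matrix(runif(n * 77), n)
  receivers <- matrix(runif(n * 70), n)
  orders <- t(vapply(1:n, function(i) sample.int(5), integer(5)))
  ev <- evaluate_population(senders, receivers, orders)
  for (i in 1:n) {
    pp <- evaluate_pair(senders[i, ], receivers[i, ], orders[i, ])
    expect_equal(as.numeric(ev$perf[i, ]), pp$trials$p_trial)
    expect_equal(ev$total[i], pp$total)
    expect_equal(as.integer(ev$onset[i, ]), pp$trials$onset)
  }
})

test_that("onset matches onset_delay applied to the log", {
  pair <- random_pair(8)
  pp <- evaluate_pair(pair$sender, pair$receiver, 1:5)
  od <- onset_delay(pp$log)
  expect_equal(od$onset[order(od$trial)], pp$trials$onset)
})

test_that("sensor_vector builds the role-specific input triple", {
  expect_equal(sensor_vector(pi / 2, "sender", food_site = 1),
               c(1, cos(pi / 2), 1))
  expect_equal(sensor_vector(0, "receiver", perceived = 0.3),
               c(0, 1, 0.3))
})
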