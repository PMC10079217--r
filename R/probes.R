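# Post-hoc counterfactual probe manipulations of evolved pairs, used to
# diagnose which mode of communication (amplitude, onset-delay, duration)
# carries the information.

# per-trial matrices (steps x trials) from a multi-trial log tibble
log_matrices <- function(log) {
  trials <- sort(unique(log$trial))
  n_steps <- max(log$step)
  stopifnot(nrow(log) == length(trials) * n_steps)
  world <- world_spec()
  ord <- order(log$trial, log$step)
  log <- log[ord, ]
  list(
    emitted = matrix(log$emitted, nrow = n_steps),
    perceived = matrix(log$perceived, nrow = n_steps),
    sender_in_nest = matrix(in_arc(log$sender_pos, world$nest),
                            nrow = n_steps),
    food_order = log$food_site[seq(1, nrow(log), by = n_steps)],
    n_steps = n_steps
  )
}

replay_result <- function(res, food_order, n_steps, options, extra = NULL) {
  m <- length(food_order)
  onset <- vapply(seq_len(m), function(k) {
    hits <- which(res$log[((k - 1) * n_steps + 1):(k * n_steps), 2] >
                    options$onset_threshold)
    if (length(hits)) as.integer(hits[1]) else NA_integer_
  }, integer(1))
  out <- structure(list(
    trials = tibble::tibble(trial = seq_len(m),
                            food_site = as.integer(food_order),
                            p_trial = as.numeric(res$perf),
                            onset = onset),
    total = sum(res$perf),
    log = tibble::tibble(
      trial = rep(seq_len(m), each = n_steps),
      step = rep(seq_len(n_steps), times = m),
      food_site = rep(as.integer(food_order), each = n_steps),
      receiver_pos = res$log[, 1],
      perceived = res$log[, 2],
      on_food = res$log[, 3] > 0
    )
  ), class = "pair_performance")
  out[names(extra)] <- extra
  out
}

#' Fixed-amplitude probe
#'
#' Re-evaluates a pair with the emitted amplitude overridden by a constant
#' (nest gating unchanged), removing any information carried by amplitude
#' variation while leaving onset and duration intact.
#'
#' @param sender,receiver Genome vectors.
#' @param amplitude Constant amplitude in `[0, 1]`.
#' @param food_order Permutation of 1..5.
#' @param treatment One of [treatments()].
#' @param options A [sim_options()].
#' @return A `"pair_performance"` object.
#' @export
probe_fixed_amplitude <- function(sender, receiver, amplitude,
                                  food_order = 1:5,
                                  treatment = "communication",
                                  options = sim_options()) {
  if (amplitude < 0 || amplitude > 1) {
    stop("`amplitude` must lie in [0, 1]", call. = FALSE)
  }
  evaluate_pair(sender, receiver, food_order, treatment, options,
                fixed_amplitude = amplitude)
}

#' Duration-lock probe
#'
#' Re-evaluates a pair with the sender frozen in place from the moment it
#' first re-enters the nest after having left it, removing any information
#' carried by the duration of nest co-presence. A sender that never leaves
#' (or never returns to) the nest moves exactly as in the control.
#'
#' @inheritParams probe_fixed_amplitude
#' @return A `"pair_performance"` object.
#' @export
probe_duration_lock <- function(sender, receiver, food_order = 1:5,
                                treatment = "communication",
                                options = sim_options()) {
  evaluate_pair(sender, receiver, food_order, treatment, options,
                duration_lock = TRUE)
}

#' Mean-amplitude replay probe
#'
#' Re-runs only the receiver, feeding it at each time step the average
#' amplitude the sender emitted at that step over the five control trials,
#' still gated by the logged sender nest presence and by the live receiver
#' nest presence. The replayed signal is therefore identical across trials in
#' amplitude profile: any performance drop indicates the receiver used
#' between-trial amplitude variation.
#'
#' @param control_log The five-trial control log tibble (from
#'   [evaluate_pair()]`$log`).
#' @param receiver Receiver genome.
#' @param options A [sim_options()].
#' @return A `"pair_performance"` object (receiver-only log columns).
#' @export
probe_mean_amplitude_replay <- function(control_log, receiver,
                                        options = sim_options()) {
  m <- log_matrices(control_log)
  if (length(m$food_order) < 2) {
    stop("the control log must contain several trials of one pair",
         call. = FALSE)
  }
  a_u <- rowMeans(m$emitted)
  avail <- a_u * m$sender_in_nest
  res <- cpp_replay_receiver(receiver, avail,
                             as.integer(m$food_order) - 1L,
                             cpp_opts(options), m$n_steps)
  replay_result(res, m$food_order, m$n_steps, options)
}

#' Onset-shift probe
#'
#' Measures the control onset-delay of the perceived signal in each trial,
#' computes the pair's mean absolute between-trial onset difference (rounded
#' to whole steps), and re-runs the receiver with the available signal
#' delayed uniformly by that many steps. Pairs whose signal was perceived in
#' fewer than two trials are not probeable and are returned with
#' `applicable = FALSE`.
#'
#' @inheritParams probe_mean_amplitude_replay
#' @return A `"pair_performance"` object with elements `shift` (steps) and
#'   `applicable`.
#' @export
probe_onset_shift <- function(control_log, receiver,
                              options = sim_options()) {
  m <- log_matrices(control_log)
  onsets <- apply(m$perceived > options$onset_threshold, 2, function(v) {
    hits <- which(v)
    if (length(hits)) hits[1] else NA_integer_
  })
  def <- onsets[!is.na(onsets)]
  if (length(def) < 2) {
    return(structure(list(trials = NULL, total = NA_real_, log = NULL,
                          shift = NA_integer_, applicable = FALSE),
                     class = "pair_performance"))
  }
  d <- abs(as.numeric(dist(def)))
  shift <- as.integer(round(mean(d)))
  avail <- m$emitted * m$sender_in_nest
  if (shift > 0) {
    avail <- rbind(matrix(0, nrow = shift, ncol = ncol(avail)),
                   avail[seq_len(m$n_steps - shift), , drop = FALSE])
  }
  res <- cpp_replay_receiver(receiver, avail,
                             as.integer(m$food_order) - 1L,
                             cpp_opts(options), m$n_steps)
  replay_result(res, m$food_order, m$n_steps, options,
                extra = list(shift = shift, applicable = TRUE))
}

#' Apply a probe across a population of pairs
#'
#' Evaluates each pair under control conditions and under the named probe,
#' using a fresh random food order per pair, and returns the paired totals.
#' For `"fixed_amplitude"` the default constant is each pair's own mean
#' emitted amplitude over the control trials (so the override removes
#' variation without moving the operating point).
#'
#' @param population A `"population"` (or list with `senders`/`receivers`
#'   genome matrices).
#' @param probe One of `"fixed_amplitude"`, `"mean_amplitude_replay"`,
#'   `"onset_shift"`, `"duration_lock"`.
#' @param treatment Treatment under which control trials are run.
#' @param options A [sim_options()].
#' @param seed Seed for the per-pair food orders.
#' @param amplitude Optional constant for `"fixed_amplitude"`.
#' @return A tibble with one row per pair: `pair`, `control`, `probe`
#'   totals and `applicable`.
#' @export
probe_population <- function(population,
                             probe = c("fixed_amplitude",
                                       "mean_amplitude_replay",
                                       "onset_shift", "duration_lock"),
                             treatment = "communication",
                             options = sim_options(), seed = 1L,
                             amplitude = NULL) {
  probe <- match.arg(probe)
  n <- nrow(population$senders)
  set.seed(seed)
  orders <- t(replicate(n, sample.int(5)))
  rows <- purrr::map(seq_len(n), function(p) {
    s <- population$senders[p, ]
    r <- population$receivers[p, ]
    ctrl <- evaluate_pair(s, r, orders[p, ], treatment, options)
    pr <- switch(probe,
      fixed_amplitude = probe_fixed_amplitude(
        s, r,
        amplitude = if (is.null(amplitude)) mean(ctrl$log$emitted)
                    else amplitude,
        food_order = orders[p, ], treatment = treatment, options = options),
      duration_lock = probe_duration_lock(s, r, orders[p, ], treatment,
                                          options),
      mean_amplitude_replay = probe_mean_amplitude_replay(ctrl$log, r,
                                                          options),
      onset_shift = probe_onset_shift(ctrl$log, r, options)
    )
    applicable <- !identical(pr$applicable, FALSE)
    tibble::tibble(pair = p, control = ctrl$total,
                   probe = if (applicable) pr$total else NA_real_,
                   applicable = applicable)
  })
  dplyr::bind_rows(rows)
}

#' Test whether a probe significantly decreased performance
#'
#' Two-sided Mann-Whitney U test of probe vs control per-pair totals, plus
#' the direction of the median change; a population counts as relying on the
#' probed communication mode when the test rejects at `alpha` and the probe
#' median is lower.
#'
#' @param probe_tbl Output of [probe_population()].
#' @param alpha Significance level (default 0.01).
#' @return A one-row tibble: medians, U statistic, `p_value`, `decreased`.
#' @export
probe_significance <- function(probe_tbl, alpha = 0.01) {
  tbl <- probe_tbl[probe_tbl$applicable & !is.na(probe_tbl$probe), ]
  cmp <- compare_treatments(tbl$probe, tbl$control)
  tibble::tibble(
    n = nrow(tbl),
    median_control = median(tbl$control),
    median_probe = median(tbl$probe),
    statistic = cmp$statistic,
    p_value = cmp$p_value,
    decreased = cmp$p_value < alpha & median(tbl$probe) < median(tbl$control)
  )
}
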