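# Trial and pair evaluation, including treatments.

#' Simulation options
#'
#' Numerical and modelling switches shared by the fast simulator and the pure
#' R reference implementation.
#'
#' @param alpha Euler integration step size (default 0.1).
#' @param input_mode How sensory values enter the network: `"direct"` (input
#'   activations are the raw sensory values; the default) or `"integrate"`
#'   (input neurons follow the same leaky update with the sensory value in
#'   place of the weighted sum). Direct pass-through keeps the sensors crisp
#'   within a trial; integrating inputs low-pass them so strongly (effective
#'   rate at most `alpha`) that within-trial reactions to food encounters are
#'   lost. The input-neuron bias and time-constant genes are inert under
#'   `"direct"`.
#' @param tau_form `"multiplicative"` (the time constant multiplies the
#'   update bracket, `s + alpha*tau*(drive - s)`; the default) or
#'   `"reciprocal"` (the conventional leaky integrator
#'   `s + (alpha/tau)*(drive - s)`, available for sensitivity checks).
#' @param onset_threshold Perceived amplitude above which the signal counts
#'   as "on" for onset-delay extraction (sigmoid outputs are never exactly
#'   zero; default `1e-6`, sensitivity alternative 0.05).
#' @param constrained_speed,constrained_direction Fixed motion imposed on
#'   senders under the constrained-sender treatment: maximum speed `pi/9`,
#'   counterclockwise, i.e. one revolution every 18 steps.
#' @param world A [world_spec()].
#' @return A list of class `"sim_options"`.
#' @export
sim_options <- function(alpha = 0.1,
                        input_mode = c("direct", "integrate"),
                        tau_form = c("multiplicative", "reciprocal"),
                        onset_threshold = 1e-6,
                        constrained_speed = world$max_speed,
                        constrained_direction = 1,
                        world = world_spec()) {
  structure(list(
    alpha = alpha,
    input_mode = match.arg(input_mode),
    tau_form = match.arg(tau_form),
    onset_threshold = onset_threshold,
    constrained_speed = constrained_speed,
    constrained_direction = constrained_direction,
    world = world
  ), class = "sim_options")
}

#' Treatments
#'
#' @return Character vector of the three evolutionary treatments.
#' @export
treatments <- function() c("communication", "no_communication",
                           "constrained_sender")

# Assemble the option list consumed by the C++ core.
cpp_opts <- function(options, treatment = "communication",
                     fixed_amplitude = NA_real_, duration_lock = FALSE) {
  treatment <- match.arg(treatment, treatments())
  if (!is.na(fixed_amplitude) &&
      (fixed_amplitude < 0 || fixed_amplitude > 1)) {
    stop("`fixed_amplitude` must lie in [0, 1]", call. = FALSE)
  }
  list(
    alpha = options$alpha,
    max_speed = options$world$max_speed,
    input_mode = match(options$input_mode, c("integrate", "direct")) - 1L,
    tau_form = match(options$tau_form, c("multiplicative", "reciprocal")) - 1L,
    treatment = match(treatment, treatments()) - 1L,
    fixed_amp = as.numeric(fixed_amplitude),
    duration_lock = isTRUE(duration_lock),
    constrained_speed = options$constrained_speed,
    constrained_dir = options$constrained_direction,
    onset_thr = options$onset_threshold
  )
}

#' Sensor vector for one agent
#'
#' Both roles sense the sine and cosine of their own position. The sender's
#' third input is its food floor sensor; the receiver's third input is the
#' perceived signal amplitude.
#'
#' @param position Agent position, radians.
#' @param role `"sender"` or `"receiver"`.
#' @param food_site Food-bearing site index (1..5), senders only.
#' @param perceived Perceived amplitude, receivers only.
#' @param world A [world_spec()].
#' @return Numeric vector of 3 sensory values.
#' @export
sensor_vector <- function(position, role = c("sender", "receiver"),
                          food_site = NULL, perceived = NULL,
                          world = world_spec()) {
  role <- match.arg(role)
  third <- if (role == "sender") {
    as.numeric(food_sensor(position, food_site, world))
  } else {
    as.numeric(perceived)
  }
  c(sin(position), cos(position), third)
}

# turn the flat C++ log matrix into the tidy per-step log
log_tibble <- function(log_mat, food_order, n_steps) {
  m <- length(food_order)
  tibble::tibble(
    trial = rep(seq_len(m), each = n_steps),
    step = rep(seq_len(n_steps), times = m),
    food_site = rep(as.integer(food_order), each = n_steps),
    sender_pos = log_mat[, 1],
    receiver_pos = log_mat[, 2],
    emitted = log_mat[, 3],
    perceived = log_mat[, 4],
    food_sensor = as.integer(log_mat[, 5]),
    on_food = log_mat[, 6] > 0
  )
}

#' Run one trial
#'
#' Simulates a 100-step trial for one sender/receiver pair with food at the
#' given site. Both agents start at position 0 with fresh network states.
#' Each step: both agents sense (the receiver's perceived amplitude uses this
#' step's emission and both agents' pre-move positions, gated by nest
#' co-presence), both networks update synchronously, then both agents move.
#' Logged positions are the pre-move positions used for sensing and scoring.
#'
#' @param sender,receiver Genome vectors.
#' @param food_site Food-bearing site index, 1..5.
#' @param treatment One of [treatments()].
#' @param options A [sim_options()].
#' @param engine `"cpp"` (fast path) or `"reference"` (naive R loops; used as
#'   the independent oracle in the test suite).
#' @return A tibble with one row per step: `trial`, `step`, `food_site`,
#'   `sender_pos`, `receiver_pos`, `emitted`, `perceived`, `food_sensor`,
#'   `on_food`.
#' @export
run_trial <- function(sender, receiver, food_site,
                      treatment = "communication",
                      options = sim_options(),
                      engine = c("cpp", "reference")) {
  engine <- match.arg(engine)
  stopifnot(food_site %in% 1:5)
  if (engine == "reference") {
    return(run_trial_reference(sender, receiver, food_site, treatment,
                               options))
  }
  n_steps <- options$world$trial_steps
  res <- cpp_run_pair(sender, receiver, as.integer(food_site) - 1L,
                      cpp_opts(options, treatment), n_steps)
  log_tibble(res$log, food_site, n_steps)
}

#' Per-trial performance from a trial log
#'
#' Performance accrues 0.01 for every one of the last 20 steps (t = 81..100)
#' the receiver spends on the food-bearing site, so a single trial is worth
#' at most 0.2 and five trials at most 1.
#'
#' @param log A trial-log tibble from [run_trial()] (one or more trials).
#' @return A tibble with `trial`, `food_site`, `steps_on_food`, `p_trial`.
#' @export
trial_performance <- function(log) {
  n_steps <- max(log$step)
  log |>
    dplyr::filter(.data$step > n_steps - 20) |>
    dplyr::group_by(.data$trial, .data$food_site) |>
    dplyr::summarise(steps_on_food = sum(.data$on_food),
                     p_trial = 0.01 * sum(.data$on_food),
                     .groups = "drop")
}

#' Evaluate one sender/receiver pair over five trials
#'
#' Runs five trials with food located once at each site in the given order,
#' resetting both networks between trials, and sums the per-trial
#' performances.
#'
#' @param sender,receiver Genome vectors.
#' @param food_order Permutation of 1..5 giving the food site per trial.
#' @param treatment One of [treatments()].
#' @param options A [sim_options()].
#' @param fixed_amplitude Optional constant overriding the emitted amplitude
#'   (probe manipulation; gating unchanged).
#' @param duration_lock If `TRUE`, the sender is frozen in place from its
#'   first re-entry into the nest (probe manipulation).
#' @return An object of class `"pair_performance"`: a list with `trials`
#'   (tibble of per-trial `food_site`, `p_trial`, `onset`), `total`, and the
#'   full step `log` tibble.
#' @export
evaluate_pair <- function(sender, receiver, food_order = 1:5,
                          treatment = "communication",
                          options = sim_options(),
                          fixed_amplitude = NA_real_,
                          duration_lock = FALSE) {
  if (!setequal(food_order, 1:5) || length(food_order) != 5) {
    stop("`food_order` must be a permutation of 1..5", call. = FALSE)
  }
  n_steps <- options$world$trial_steps
  res <- cpp_run_pair(sender, receiver, as.integer(food_order) - 1L,
                      cpp_opts(options, treatment, fixed_amplitude,
                               duration_lock),
                      n_steps)
  structure(list(
    trials = tibble::tibble(trial = 1:5,
                            food_site = as.integer(food_order),
                            p_trial = as.numeric(res$perf),
                            onset = as.integer(res$onset)),
    total = sum(res$perf),
    log = log_tibble(res$log, food_order, n_steps)
  ), class = "pair_performance")
}

#' @export
print.pair_performance <- function(x, ...) {
  cat("<pair_performance> total =", format(x$total), "\n")
  print(x$trials)
  invisible(x)
}

#' Evaluate a whole population of pairs
#'
#' Fast path over genome matrices: each row of `senders` is evaluated with
#' the same row of `receivers` over the five food placements in that row of
#' `food_orders`.
#'
#' @param senders,receivers Genome matrices (`n_pairs` rows).
#' @param food_orders Integer matrix `n_pairs x 5`; each row a permutation of
#'   1..5. Defaults to `1:5` for every pair.
#' @param treatment One of [treatments()].
#' @param options A [sim_options()].
#' @return A list with `perf` (`n x 5` per-trial performances), `total`
#'   (length-n vector), `onset` (`n x 5` first step at which the receiver
#'   perceived the signal; `NA` if never).
#' @export
evaluate_population <- function(senders, receivers, food_orders = NULL,
                                treatment = "communication",
                                options = sim_options()) {
  n <- nrow(senders)
  if (is.null(food_orders)) {
    food_orders <- matrix(rep(1:5, each = n), nrow = n)
  }
  stopifnot(nrow(receivers) == n, nrow(food_orders) == n)
  res <- cpp_eval_population(senders, receivers,
                             matrix(as.integer(food_orders) - 1L, nrow = n),
                             cpp_opts(options, treatment),
                             options$world$trial_steps)
  list(perf = res$perf, total = rowSums(res$perf), onset = res$onset)
}
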