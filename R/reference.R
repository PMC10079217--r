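# Naive per-neuron, per-step R simulator. Deliberately loop-based and built
# from the exported world/ctrnn primitives: it is the independent oracle
# against which the compiled fast path is checked (agreement to 1e-12).

run_trial_reference <- function(sender, receiver, food_site,
                                treatment = "communication",
                                options = sim_options(),
                                fixed_amplitude = NA_real_,
                                duration_lock = FALSE) {
  treatment <- match.arg(treatment, treatments())
  world <- options$world
  pS <- decode_genome(sender, "sender")
  pR <- decode_genome(receiver, "receiver")
  stS <- new_network_state(pS)
  stR <- new_network_state(pR)
  pos_s <- 0; pos_r <- 0
  frozen <- FALSE; was_outside <- FALSE
  n_steps <- world$trial_steps
  out <- matrix(NA_real_, nrow = n_steps, ncol = 6)
  for (t in seq_len(n_steps)) {
    food <- as.numeric(food_sensor(pos_s, food_site, world))
    stS <- ctrnn_step(pS, stS, c(sin(pos_s), cos(pos_s), food), options)
    y_out_s <- stS$y[pS$arch$n_inputs + pS$arch$n_hidden + 1:3]
    emitted <- if (!is.na(fixed_amplitude)) fixed_amplitude else y_out_s[3]
    avail <- if (in_arc(pos_s, world$nest)) emitted else 0
    perceived <- if (treatment == "no_communication") 0 else {
      if (in_arc(pos_r, world$nest)) avail else 0
    }
    stR <- ctrnn_step(pR, stR, c(sin(pos_r), cos(pos_r), perceived), options)
    y_out_r <- stR$y[pR$arch$n_inputs + pR$arch$n_hidden + 1:2]
    on_food <- in_arc(pos_r, world$sites[[food_site]])
    out[t, ] <- c(pos_s, pos_r, emitted, perceived, food, on_food)
    # movement
    if (treatment == "constrained_sender") {
      pos_s <- normalize_angle(pos_s + options$constrained_direction *
                                 options$constrained_speed)
    } else {
      if (duration_lock && !frozen) {
        if (!in_arc(pos_s, world$nest)) was_outside <- TRUE
        else if (was_outside) frozen <- TRUE
      }
      if (!frozen) {
        mc <- motor_command(y_out_s[1:2], world$max_speed)
        pos_s <- normalize_angle(pos_s + mc$direction * mc$speed)
      }
    }
    mc <- motor_command(y_out_r, world$max_speed)
    pos_r <- normalize_angle(pos_r + mc$direction * mc$speed)
  }
  tibble::tibble(
    trial = 1L,
    step = seq_len(n_steps),
    food_site = as.integer(food_site),
    sender_pos = out[, 1],
    receiver_pos = out[, 2],
    emitted = out[, 3],
    perceived = out[, 4],
    food_sensor = as.integer(out[, 5]),
    on_food = out[, 6] > 0
  )
}
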