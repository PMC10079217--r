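# Genome encoding/decoding and CTRNN dynamics (reference R implementation;
# the fast path lives in src/sim.cpp and is cross-checked against this one).

#' Network architecture for a role
#'
#' Both roles use 3 input neurons (sine and cosine of own position plus a
#' role-specific third sensor), 5 fully recurrent hidden neurons, and motor
#' outputs. The sender has a third output neuron for the signal amplitude.
#'
#' @param role `"sender"` or `"receiver"`.
#' @return A list with `n_inputs`, `n_hidden`, `n_outputs`, `n_neurons`,
#'   `role`.
#' @export
architecture <- function(role = c("sender", "receiver")) {
  role <- match.arg(role)
  n_out <- if (role == "sender") 3L else 2L
  list(role = role, n_inputs = 3L, n_hidden = 5L, n_outputs = n_out,
       n_neurons = 3L + 5L + n_out)
}

#' Genome length implied by an architecture
#'
#' Counts one gene per connection weight (input to hidden, recurrent hidden,
#' hidden to output) plus one bias and one time-constant gene per neuron:
#' 77 genes for a sender, 70 for a receiver.
#'
#' @param arch An [architecture()].
#' @return Integer genome length.
#' @export
genome_length <- function(arch) {
  with(arch, n_inputs * n_hidden + n_hidden^2 + n_hidden * n_outputs +
         2L * n_neurons)
}

#' Decode a genome into network parameters
#'
#' Genes are reals in `[0, 1]`, laid out as: input-to-hidden weights
#' (column-major by input neuron), recurrent hidden weights (column-major by
#' presynaptic neuron), hidden-to-output weights (column-major by presynaptic
#' hidden neuron), then one bias per neuron and one time constant per neuron
#' (neuron order: inputs, hidden, outputs). Weights map linearly onto
#' `[-4, 4]` (`8g - 4`), biases onto `[-2, 2]` (`4g - 2`) and time constants
#' onto `[0.1, 1.0]` (`0.1 + 0.9g`). There are no input-to-output or
#' output-to-output connections.
#'
#' @param genome Numeric vector of genes in `[0, 1]`.
#' @param role `"sender"` or `"receiver"` (fixes the expected length).
#' @return A list of class `"network_params"` with `W_ih`, `W_hh`, `W_ho`,
#'   `theta`, `tau` and the `arch`.
#' @export
decode_genome <- function(genome, role = c("sender", "receiver")) {
  arch <- architecture(role)
  glen <- genome_length(arch)
  if (length(genome) != glen) {
    stop(sprintf("genome length %d does not match the %s architecture (%d)",
                 length(genome), arch$role, glen), call. = FALSE)
  }
  if (any(genome < 0 | genome > 1)) {
    stop("all genes must lie in [0, 1]", call. = FALSE)
  }
  ni <- arch$n_inputs; nh <- arch$n_hidden; no <- arch$n_outputs
  n <- arch$n_neurons
  k <- 0L
  take <- function(m) {
    out <- genome[(k + 1L):(k + m)]
    k <<- k + m
    out
  }
  structure(list(
    W_ih = matrix(8 * take(nh * ni) - 4, nrow = nh, ncol = ni),
    W_hh = matrix(8 * take(nh * nh) - 4, nrow = nh, ncol = nh),
    W_ho = matrix(8 * take(no * nh) - 4, nrow = no, ncol = nh),
    theta = 4 * take(n) - 2,
    tau = 0.1 + 0.9 * take(n),
    arch = arch
  ), class = "network_params")
}

#' Re-encode network parameters into a genome
#'
#' Exact inverse of [decode_genome()] (the gene maps are linear bijections).
#'
#' @param params A `"network_params"` object.
#' @return Numeric genome vector.
#' @export
encode_genome <- function(params) {
  c((as.vector(params$W_ih) + 4) / 8,
    (as.vector(params$W_hh) + 4) / 8,
    (as.vector(params$W_ho) + 4) / 8,
    (params$theta + 2) / 4,
    (params$tau - 0.1) / 0.9)
}

#' Fresh network state at the start of a trial
#'
#' All internal states are reset to 0, so initial activations are
#' `sigmoid(theta)`. Networks are reset between the five trials of an
#' evaluation.
#'
#' @param params A `"network_params"` object.
#' @return A list with `s` (internal states) and `y` (activations).
#' @export
new_network_state <- function(params) {
  list(s = rep(0, params$arch$n_neurons),
       y = plogis_(params$theta))
}

# logistic sigmoid; written out so the C++ core and this reference share the
# exact same expression
plogis_ <- function(x) 1 / (1 + exp(-x))

#' One synchronous CTRNN update
#'
#' Advances every neuron by one simulation step. Input neurons follow the
#' same leaky update with the raw sensory value in place of the weighted sum;
#' hidden neurons then integrate the fresh input activations together with
#' the previous hidden activations; output neurons integrate the fresh hidden
#' activations. The state update is the Euler increment
#' `s <- s + alpha * tau * (drive - s)` with the time constant multiplying
#' the bracket (see [sim_options()] for the conventional `alpha/tau` form),
#' and activations are `y = sigmoid(s + theta)`.
#'
#' @param params A `"network_params"` object.
#' @param state State list from [new_network_state()] or a previous call.
#' @param inputs Numeric vector of 3 sensory values.
#' @param options A [sim_options()] list.
#' @return Updated state list.
#' @export
ctrnn_step <- function(params, state, inputs, options = sim_options()) {
  arch <- params$arch
  if (length(inputs) != arch$n_inputs) {
    stop("`inputs` must have length ", arch$n_inputs, call. = FALSE)
  }
  ni <- arch$n_inputs; nh <- arch$n_hidden; no <- arch$n_outputs
  s <- state$s; y <- state$y
  rate <- function(i) {
    if (options$tau_form == "multiplicative") options$alpha * params$tau[i]
    else options$alpha / params$tau[i]
  }
  for (i in seq_len(ni)) {
    if (options$input_mode == "direct") {
      y[i] <- inputs[i]
    } else {
      s[i] <- s[i] + rate(i) * (inputs[i] - s[i])
      y[i] <- plogis_(s[i] + params$theta[i])
    }
  }
  y_h_prev <- y[ni + seq_len(nh)]
  y_h_new <- numeric(nh)
  for (h in seq_len(nh)) {
    drive <- 0
    for (i in seq_len(ni)) drive <- drive + params$W_ih[h, i] * y[i]
    for (j in seq_len(nh)) drive <- drive + params$W_hh[h, j] * y_h_prev[j]
    idx <- ni + h
    s[idx] <- s[idx] + rate(idx) * (drive - s[idx])
    y_h_new[h] <- plogis_(s[idx] + params$theta[idx])
  }
  y[ni + seq_len(nh)] <- y_h_new
  for (o in seq_len(no)) {
    drive <- 0
    for (h in seq_len(nh)) drive <- drive + params$W_ho[o, h] * y_h_new[h]
    idx <- ni + nh + o
    s[idx] <- s[idx] + rate(idx) * (drive - s[idx])
    y[idx] <- plogis_(s[idx] + params$theta[idx])
  }
  list(s = s, y = y)
}

#' Motor command from the two motor activations
#'
#' Speed is the absolute difference of the two motor outputs scaled by the
#' maximum speed; direction is the sign of the difference (+1 on an exact
#' tie, where the speed is zero anyway).
#'
#' @param y_motor Numeric vector of two motor activations in `(0, 1)`.
#' @param max_speed Maximum angular speed in radians per step.
#' @return A list with `speed` and `direction`.
#' @export
motor_command <- function(y_motor, max_speed = world_spec()$max_speed) {
  stopifnot(length(y_motor) == 2)
  d <- y_motor[1] - y_motor[2]
  list(speed = abs(d) * max_speed, direction = if (d >= 0) 1 else -1)
}

#' Hand-constructed fixture genomes
#'
#' Builds genomes whose decoded networks provably produce a named behavior,
#' for unit tests and analytic checks:
#' \describe{
#'   \item{`stationary`}{All genes 0.5: every weight and bias is 0, both
#'     motor activations equal 0.5 at every step, so the agent never moves.}
#'   \item{`constant_speed`}{All weights zero; opposite motor biases chosen
#'     so the motor difference is exactly `speed / max_speed` from the first
#'     step on. Achievable fractions are limited by the bias range to about
#'     0.76 of the maximum speed.}
#'   \item{`constant_full_speed_ccw`}{Saturating excitation (maximal weights
#'     and biases toward motor 1, maximally negative toward motor 2): the
#'     speed converges to the maximum within machine precision after a short
#'     transient.}
#'   \item{`constant_amplitude`}{Sender only. All weights zero and the signal
#'     output bias set to `qlogis(amplitude)`, so the emitted amplitude is
#'     exactly constant from step one. Requires `amplitude` within
#'     `plogis(c(-2, 2))`, about `[0.12, 0.88]`.}
#' }
#'
#' @param role `"sender"` or `"receiver"`.
#' @param behavior One of `"stationary"`, `"constant_speed"`,
#'   `"constant_full_speed_ccw"`, `"constant_amplitude"`.
#' @param speed Target speed (radians/step) for `"constant_speed"`.
#' @param direction +1 or -1 for `"constant_speed"`.
#' @param amplitude Emitted amplitude for `"constant_amplitude"`.
#' @param world A [world_spec()] (provides `max_speed`).
#' @return A genome vector of the role's length.
#' @export
make_fixture_genome <- function(role = c("sender", "receiver"),
                                behavior = c("stationary", "constant_speed",
                                             "constant_full_speed_ccw",
                                             "constant_amplitude"),
                                speed = NULL, direction = 1,
                                amplitude = NULL, world = world_spec()) {
  role <- match.arg(role)
  behavior <- match.arg(behavior)
  arch <- architecture(role)
  g <- rep(0.5, genome_length(arch))
  ni <- arch$n_inputs; nh <- arch$n_hidden; no <- arch$n_outputs
  n_w <- ni * nh + nh * nh + nh * no
  bias_gene <- function(neuron) n_w + neuron            # neuron index 1..n
  tau_gene <- function(neuron) n_w + arch$n_neurons + neuron
  out_neuron <- function(o) ni + nh + o
  if (behavior == "stationary") {
    return(g)
  }
  if (behavior == "constant_amplitude") {
    if (role != "sender") stop("only senders emit a signal", call. = FALSE)
    stopifnot(!is.null(amplitude))
    theta <- stats::qlogis(amplitude)
    if (abs(theta) > 2) {
      stop("`amplitude` must lie within plogis(c(-2, 2))", call. = FALSE)
    }
    g[bias_gene(out_neuron(3))] <- (theta + 2) / 4
    return(g)
  }
  if (behavior == "constant_speed") {
    stopifnot(!is.null(speed), direction %in% c(-1, 1))
    frac <- speed / world$max_speed
    if (frac < 0 || frac > 2 * plogis_(2) - 1) {
      stop("requested speed outside the bias-only achievable range",
           call. = FALSE)
    }
    theta <- stats::qlogis((1 + frac) / 2)
    hi <- if (direction > 0) 1 else 2
    lo <- if (direction > 0) 2 else 1
    g[bias_gene(out_neuron(hi))] <- (theta + 2) / 4
    g[bias_gene(out_neuron(lo))] <- (-theta + 2) / 4
    return(g)
  }
  # constant_full_speed_ccw: drive hidden neurons into saturation and feed
  # them with maximal opposite-sign weights into the two motor outputs
  g[seq_len(ni * nh)] <- 1                          # input -> hidden at +4
  g[ni * nh + seq_len(nh * nh)] <- 1                # recurrent at +4
  who_gene <- function(o, h) ni * nh + nh * nh + (h - 1L) * no + o
  for (h in seq_len(nh)) {
    g[who_gene(1, h)] <- 1                          # hidden -> motor1 at +4
    g[who_gene(2, h)] <- 0                          # hidden -> motor2 at -4
  }
  for (h in seq_len(nh)) g[bias_gene(ni + h)] <- 1  # hidden biases at +2
  g[bias_gene(out_neuron(1))] <- 1
  g[bias_gene(out_neuron(2))] <- 0
  g[(n_w + arch$n_neurons + 1L):(n_w + 2L * arch$n_neurons)] <- 1  # tau = 1
  g
}
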