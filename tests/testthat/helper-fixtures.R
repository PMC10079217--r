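# Shared fixtures: tiny genomes, constructed logs, and a memoised desk-scale
# sweep (expensive runs are shared between the scaled-simulation and
# full-scale-direction acceptance blocks).

random_pair <- function(seed = 1) {
  set.seed(seed)
  list(sender = runif(genome_length(architecture("sender"))),
       receiver = runif(genome_length(architecture("receiver"))))
}

# a receiver that cruises at constant speed v so that it sits inside the
# given food site during the scored steps 81..100 (pre-move positions
# v * (t - 1))
parked_receiver <- function(food_site, world = world_spec()) {
  centers <- abs(world$site_centers)
  direction <- sign(world$site_centers[food_site])
  if (direction == 0) direction <- 1
  c0 <- centers[food_site]
  lo <- (c0 - pi / 8) / 80
  hi <- (c0 + pi / 8) / 99
  make_fixture_genome("receiver", "constant_speed", speed = (lo + hi) / 2,
                      direction = direction)
}

# hand-built five-trial log with prescribed per-step emitted amplitudes and
# a flag saying whether each trial counts as "food found"
synthetic_log <- function(emitted, found = rep(TRUE, ncol(emitted)),
                          n_steps = nrow(emitted)) {
  m <- ncol(emitted)
  tibble::tibble(
    trial = rep(seq_len(m), each = n_steps),
    step = rep(seq_len(n_steps), times = m),
    food_site = rep(seq_len(m), each = n_steps),
    sender_pos = 0,
    receiver_pos = rep(purrr::map(seq_len(m), function(k) {
      w <- world_spec()
      on <- c(rep(FALSE, n_steps - 20), rep(found[k], 20))
      ifelse(on, w$site_centers[k], 0)
    }) |> unlist(), times = 1),
    emitted = as.vector(emitted),
    perceived = 0,
    food_sensor = 0L,
    on_food = as.vector(vapply(seq_len(m), function(k) {
      c(rep(FALSE, n_steps - 20), rep(found[k], 20))
    }, logical(n_steps)))
  )
}

# desk-scale sweep shared by the acceptance tests: 10 replicates of each
# treatment at 100 pairs x 500 generations, run once per test session
desk_sweep <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    runs <- list()
    for (tr in treatments()) {
      runs[[tr]] <- lapply(1:10, function(seed) {
        run_evolution(evolution_config(generations = 500, n_pairs = 100,
                                       treatment = tr), seed = seed)
      })
    }
    cache <<- runs
    runs
  }
})
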