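# The generational loop: initialization, tournament selection, mutation,
# history logging, checkpoint/resume.

#' Evolution configuration
#'
#' Defaults are the full-scale study conditions: 1000 pairs evolved for
#' 25000 generations with tournament size 10 and a baseline mutation rate of
#' 0.5 expected mutations per genome per generation. Use
#' [scale_preset()]`("desk_small")` for a workstation-scale configuration.
#'
#' @param generations Number of generations.
#' @param n_pairs Number of sender/receiver pairs.
#' @param tournament_size Tournament size for parent selection.
#' @param mu Baseline mutation rate: expected mutations per genome per
#'   generation; the per-gene rate is `mu / genome_length`.
#' @param mutation_sd Standard deviation of the Gaussian mutation kernel.
#' @param mutation_center `"gene"` (Gaussian centered on the current gene
#'   value, the default) or `"midpoint"` (centered on 0.5); values are
#'   reflected back into `[0, 1]`.
#' @param treatment One of [treatments()].
#' @param repair_each_generation If `TRUE` (default) offspring are randomly
#'   re-paired every generation; if `FALSE` pairings persist.
#' @param keep_pair_perf If `TRUE` (default) the full per-generation,
#'   per-pair performance matrix is kept in the history (needed for the
#'   significance-based milestone).
#' @param options A [sim_options()].
#' @return A list of class `"evolution_config"`.
#' @export
evolution_config <- function(generations = 25000, n_pairs = 1000,
                             tournament_size = 10, mu = 0.5,
                             mutation_sd = 0.1,
                             mutation_center = c("gene", "midpoint"),
                             treatment = "communication",
                             repair_each_generation = TRUE,
                             keep_pair_perf = TRUE,
                             options = sim_options()) {
  treatment <- match.arg(treatment, treatments())
  mutation_center <- match.arg(mutation_center)
  stopifnot(generations >= 1, n_pairs >= 2, tournament_size >= 1,
            tournament_size <= n_pairs, mu > 0, mutation_sd > 0)
  structure(list(generations = as.integer(generations),
                 n_pairs = as.integer(n_pairs),
                 tournament_size = as.integer(tournament_size),
                 mu = mu, mutation_sd = mutation_sd,
                 mutation_center = mutation_center,
                 treatment = treatment,
                 repair_each_generation = isTRUE(repair_each_generation),
                 keep_pair_perf = isTRUE(keep_pair_perf),
                 options = options),
            class = "evolution_config")
}

#' Initialize a population
#'
#' Every gene is drawn uniformly from `[0, 1]`; each sender is randomly
#' paired with a receiver (rows of the two matrices form the pairs).
#'
#' @param config An [evolution_config()].
#' @param seed Integer seed (ignored if `streams` is given).
#' @param streams Optionally, an existing [rng_streams()] object whose
#'   `init` stream supplies the draws.
#' @return A list of class `"population"` with genome matrices `senders`
#'   (`n_pairs x 77`) and `receivers` (`n_pairs x 70`).
#' @export
init_population <- function(config, seed = 1L, streams = NULL) {
  if (is.null(streams)) streams <- rng_streams(seed)
  n <- config$n_pairs
  ls <- genome_length(architecture("sender"))
  lr <- genome_length(architecture("receiver"))
  with_stream(streams, "init", {
    senders <- matrix(runif(n * ls), nrow = n, ncol = ls)
    receivers <- matrix(runif(n * lr), nrow = n, ncol = lr)
    receivers <- receivers[sample.int(n), , drop = FALSE]
    structure(list(senders = senders, receivers = receivers),
              class = "population")
  })
}

#' Per-gene mutation probability
#'
#' The per-gene rate is the baseline rate divided by the genome length, so
#' the expected number of mutations per genome per generation equals `mu`
#' for both roles despite their different genome sizes.
#'
#' @param genome_length Genome length (77 sender, 70 receiver).
#' @param mu Baseline mutation rate (default 0.5).
#' @return Per-gene mutation probability.
#' @export
mutation_rate <- function(genome_length, mu = 0.5) {
  stopifnot(genome_length > 0)
  mu / genome_length
}

# reflect real values into [0, 1] (triangle fold; exact for any input)
reflect_unit <- function(x) {
  r <- x %% 2
  ifelse(r > 1, 2 - r, r)
}

#' Mutate a matrix of genomes
#'
#' Each gene independently mutates with probability `rate`; a mutated gene is
#' replaced by a draw from a normal distribution centered on its current
#' value (or on 0.5 with `center = "midpoint"`) with standard deviation `sd`,
#' reflected back into `[0, 1]`. Unmutated genes are untouched.
#'
#' @param genomes Genome matrix (or vector).
#' @param rate Per-gene mutation probability.
#' @param sd Mutation kernel standard deviation.
#' @param center `"gene"` or `"midpoint"`.
#' @return Mutated genomes, same shape.
#' @export
mutate_genomes <- function(genomes, rate, sd = 0.1,
                           center = c("gene", "midpoint")) {
  center <- match.arg(center)
  stopifnot(rate >= 0, rate <= 1)
  hit <- runif(length(genomes)) < rate
  n_hit <- sum(hit)
  if (n_hit > 0) {
    mean_ <- if (center == "gene") genomes[hit] else 0.5
    genomes[hit] <- reflect_unit(rnorm(n_hit, mean = mean_, sd = sd))
  }
  genomes
}

#' Tournament selection
#'
#' Each of `n_select` tournaments samples `k` candidates uniformly with
#' replacement and returns the index of the candidate with maximal
#' performance; ties are broken uniformly at random. With `k = 1` this
#' degenerates to uniform random selection.
#'
#' @param performances Numeric vector of pair performances.
#' @param k Tournament size.
#' @param n_select Number of parents to select (default: population size).
#' @return Integer vector of selected indices.
#' @export
tournament_select <- function(performances, k = 10,
                              n_select = length(performances)) {
  n <- length(performances)
  if (n == 0) stop("empty population", call. = FALSE)
  stopifnot(k >= 1, k <= n)
  idx <- matrix(sample.int(n, n_select * k, replace = TRUE),
                nrow = n_select, ncol = k)
  win_col <- max.col(matrix(performances[idx], nrow = n_select),
                     ties.method = "random")
  idx[cbind(seq_len(n_select), win_col)]
}

#' Produce the next generation
#'
#' Senders and receivers are selected in separate tournament streams, each
#' individual scored by its pair's total performance; offspring are mutated
#' at the role-specific per-gene rate and (by default) randomly re-paired.
#'
#' @param population A `"population"`.
#' @param totals Per-pair total performances.
#' @param config An [evolution_config()].
#' @param streams An [rng_streams()] object (uses the `selection` and
#'   `mutation` streams).
#' @return The next `"population"`.
#' @export
next_generation <- function(population, totals, config, streams) {
  n <- config$n_pairs
  k <- config$tournament_size
  sel <- with_stream(streams, "selection", {
    list(s = tournament_select(totals, k, n),
         r = tournament_select(totals, k, n),
         pairing = if (config$repair_each_generation) sample.int(n)
                   else seq_len(n))
  })
  senders <- population$senders[sel$s, , drop = FALSE]
  receivers <- population$receivers[sel$r, , drop = FALSE][sel$pairing, ,
                                                           drop = FALSE]
  with_stream(streams, "mutation", {
    senders <- mutate_genomes(senders, mutation_rate(ncol(senders), config$mu),
                              config$mutation_sd, config$mutation_center)
    receivers <- mutate_genomes(receivers,
                                mutation_rate(ncol(receivers), config$mu),
                                config$mutation_sd, config$mutation_center)
    NULL
  })
  structure(list(senders = senders, receivers = receivers),
            class = "population")
}

# spread (max - min) of the defined onsets of one pair's five trials;
# NA unless at least two trials have a defined onset
onset_spread <- function(onsets) {
  o <- onsets[!is.na(onsets)]
  if (length(o) < 2) NA_real_ else max(o) - min(o)
}

#' Run an evolutionary experiment
#'
#' Executes the full generational loop: evaluate every pair over five trials
#' (fresh random food order per pair per generation), select parents by
#' tournaments run separately on senders and receivers, mutate, re-pair, and
#' log. Deterministic given `seed`; optionally checkpoints to disk and
#' resumes from the last checkpoint.
#'
#' @param config An [evolution_config()].
#' @param seed Integer master seed, expanded into independent named streams
#'   (init, food order, selection, mutation).
#' @param checkpoint_path Optional `.rds` path for checkpoints.
#' @param checkpoint_every Write a checkpoint every this many generations.
#' @param resume If `TRUE` and `checkpoint_path` exists, continue from it.
#' @param verbose Print progress every 100 generations.
#' @return An object of class `"evolution_history"`: `summary` (one tibble
#'   row per generation), `perf` (generation x pair total-performance
#'   matrix, if kept), `best_onsets` (generation x 5 onset-delays of the
#'   generation's best pair), the final `population`, `config` and `seed`.
#' @export
run_evolution <- function(config, seed = 1L, checkpoint_path = NULL,
                          checkpoint_every = Inf, resume = FALSE,
                          verbose = FALSE) {
  gens <- config$generations
  n <- config$n_pairs
  if (resume && !is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    state <- readRDS(checkpoint_path)
    if (!identical(state$seed, as.integer(seed))) {
      stop("checkpoint was written under a different seed", call. = FALSE)
    }
    streams <- new.env(parent = emptyenv())
    streams$states <- state$streams_states
    class(streams) <- "rng_streams"
    population <- state$population
    start_gen <- state$next_gen
    summaries <- state$summaries
    perf_mat <- state$perf_mat
    best_onsets <- state$best_onsets
  } else {
    streams <- rng_streams(seed)
    population <- init_population(config, streams = streams)
    start_gen <- 1L
    summaries <- vector("list", gens)
    perf_mat <- if (config$keep_pair_perf) {
      matrix(NA_real_, nrow = gens, ncol = n)
    } else NULL
    best_onsets <- matrix(NA_integer_, nrow = gens, ncol = 5)
  }
  for (gen in start_gen:gens) {
    food <- with_stream(streams, "food", {
      u <- matrix(runif(n * 5), nrow = n)
      t(apply(u, 1, order))
    })
    ev <- evaluate_population(population$senders, population$receivers,
                              food, config$treatment, config$options)
    totals <- ev$total
    best <- which.max(totals)
    spreads <- apply(ev$onset, 1, onset_spread)
    summaries[[gen]] <- tibble::tibble(
      generation = gen,
      mean_perf = mean(totals),
      q25 = unname(quantile(totals, 0.25)),
      median_perf = median(totals),
      q75 = unname(quantile(totals, 0.75)),
      max_perf = max(totals),
      best_pair = as.integer(best),
      onset_spread_best = onset_spread(ev$onset[best, ]),
      onset_spread_median = if (all(is.na(spreads))) NA_real_
                            else median(spreads, na.rm = TRUE)
    )
    if (!is.null(perf_mat)) perf_mat[gen, ] <- totals
    best_onsets[gen, ] <- ev$onset[best, ]
    if (gen < gens) {
      population <- next_generation(population, totals, config, streams)
    }
    if (!is.null(checkpoint_path) && is.finite(checkpoint_every) &&
        gen %% checkpoint_every == 0 && gen < gens) {
      saveRDS(list(seed = as.integer(seed),
                   streams_states = streams$states,
                   population = population, next_gen = gen + 1L,
                   summaries = summaries, perf_mat = perf_mat,
                   best_onsets = best_onsets),
              checkpoint_path)
    }
    if (verbose && gen %% 100 == 0) {
      message(sprintf("gen %d: mean %.3f max %.3f", gen,
                      mean(totals), max(totals)))
    }
  }
  structure(list(
    summary = dplyr::bind_rows(summaries),
    perf = perf_mat,
    best_onsets = best_onsets,
    population = population,
    config = config,
    seed = as.integer(seed)
  ), class = "evolution_history")
}

#' @export
print.evolution_history <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "<evolution_history> %s: %d pairs, %d generations (seed %d)\n",
    x$config$treatment, x$config$n_pairs, x$config$generations, x$seed))
  cat(sprintf("final mean performance %.3f (max %.3f)\n",
              last$mean_perf, last$max_perf))
  invisible(x)
}
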