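# broom-style tidiers for the fitted/experiment objects.

#' Tidy an evolution history
#'
#' @param x An `"evolution_history"`.
#' @param ... Unused.
#' @return The per-generation summary tibble.
#' @export
tidy.evolution_history <- function(x, ...) x$summary

#' One-row summary of an evolution history
#'
#' @param x An `"evolution_history"`.
#' @param ... Unused.
#' @return A one-row tibble: treatment, scale, seed, final mean/max
#'   performance and the two milestone generations.
#' @export
glance.evolution_history <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  tibble::tibble(
    treatment = x$config$treatment,
    n_pairs = x$config$n_pairs,
    generations = x$config$generations,
    seed = x$seed,
    final_mean = last$mean_perf,
    final_max = last$max_perf,
    gen_onset_variation = first_onset_variation_generation(x),
    gen_exceeds_0.2 = if (is.null(x$perf)) NA_integer_
                      else first_exceeds_threshold_generation(x)
  )
}

#' Tidy a pair evaluation
#'
#' @param x A `"pair_performance"`.
#' @param ... Unused.
#' @return The per-trial tibble (`trial`, `food_site`, `p_trial`, `onset`).
#' @export
tidy.pair_performance <- function(x, ...) x$trials

#' One-row summary of a pair evaluation
#'
#' @param x A `"pair_performance"`.
#' @param ... Unused.
#' @return A one-row tibble with the total performance and trial count.
#' @export
glance.pair_performance <- function(x, ...) {
  tibble::tibble(total = x$total,
                 n_trials = if (is.null(x$trials)) 0L else nrow(x$trials))
}
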