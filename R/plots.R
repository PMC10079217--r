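# ggplot2 convenience plots for the main result types.

#' Plot a performance trajectory
#'
#' Mean population performance per generation with the interquartile band.
#'
#' @param object An `"evolution_history"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evolution_history <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_perf)) +
    ggplot2::labs(x = "generation", y = "performance",
                  title = object$config$treatment) +
    ggplot2::ylim(0, 1)
}

#' Plot a success histogram
#'
#' Share of receivers that found the food in 0..5 of the five trials.
#'
#' @param hist_tbl Output of [success_histogram()].
#' @return A ggplot object.
#' @export
plot_success_histogram <- function(hist_tbl) {
  ggplot2::ggplot(hist_tbl,
                  ggplot2::aes(x = factor(.data$successes),
                               y = .data$share)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "trials with food found (of 5)",
                  y = "share of receivers")
}

#' Plot agent trajectories for a set of trials
#'
#' Sender and receiver angular positions over the trial steps, one panel per
#' trial, with the nest band marked.
#'
#' @param log A trial-log tibble.
#' @return A ggplot object.
#' @export
plot_trial <- function(log) {
  long <- log |>
    tidyr::pivot_longer(cols = c("sender_pos", "receiver_pos"),
                        names_to = "agent", values_to = "position") |>
    dplyr::mutate(agent = sub("_pos$", "", .data$agent))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$position,
                                     color = .data$agent)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = -pi / 4, ymax = pi / 4, alpha = 0.12) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_wrap(~trial, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "angular position [-pi, pi)")
}
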