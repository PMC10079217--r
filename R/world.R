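# Geometry and physics of the one-dimensional circular environment.

#' Normalize an angle to [-pi, pi)
#'
#' All positions on the circular world live in the half-open interval
#' \code{[-pi, pi)}; arithmetic is modulo \code{2*pi} and \code{pi} is
#' identified with \code{-pi}. Normalization is idempotent.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of the same length, each value in \code{[-pi, pi)}.
#' @export
#' @examples
#' normalize_angle(c(0, pi, -pi, 3 * pi))
normalize_angle <- function(x) {
  x - 2 * pi * floor((x + pi) / (2 * pi))
}

#' Construct an arc on the circle
#'
#' An arc is the half-open interval \code{[center - length/2,
#' center + length/2)}, wrap-aware at the \code{+/-pi} seam. The half-open
#' convention (closed at the lower edge, open at the upper) guarantees that
#' adjacent arcs whose edges touch do not overlap.
#'
#' @param center Arc center, radians (normalized internally).
#' @param length Arc length, radians, must be positive.
#' @return A list of class \code{"arc"} with fields \code{center} and
#'   \code{length}.
#' @export
arc <- function(center, length) {
  stopifnot(is.numeric(center), is.numeric(length), length > 0)
  structure(list(center = normalize_angle(center), length = length),
            class = "arc")
}

#' Test whether positions lie inside an arc
#'
#' Membership is wrap-aware and uses the half-open convention of [arc()]:
#' the lower edge belongs to the arc, the upper edge does not.
#'
#' @param position Numeric vector of angles (radians; normalized internally,
#'   so adding any multiple of \code{2*pi} does not change the answer).
#' @param arc An [arc()].
#' @return Logical vector.
#' @export
#' @examples
#' w <- world_spec()
#' in_arc(0, w$nest)      # nest is centered on 0
#' in_arc(pi, w$nest)     # antipodal point
in_arc <- function(position, arc) {
  d <- normalize_angle(position - arc$center)
  d >= -arc$length / 2 & d < arc$length / 2
}

#' The world specification
#'
#' Five non-overlapping foraging sites of length \code{pi/4} centered at
#' \code{pi/2, 3*pi/4, pi, -3*pi/4, -pi/2} (tiling the half-circle opposite
#' the nest), a nest (communication area) centered on 0 of width \code{pi/2}
#' (from \code{-pi/4} to \code{pi/4}), a maximum angular speed of \code{pi/9}
#' radians per step, and 100-step trials. These constants are the single
#' source of truth shared by the simulator, the analysis layer and the tests.
#'
#' @return A list of class \code{"world_spec"} with fields \code{sites}
#'   (list of 5 arcs), \code{site_centers}, \code{nest}, \code{max_speed},
#'   \code{trial_steps}.
#' @export
world_spec <- function() {
  centers <- c(pi / 2, 3 * pi / 4, pi, -3 * pi / 4, -pi / 2)
  structure(list(
    sites = lapply(centers, arc, length = pi / 4),
    site_centers = normalize_angle(centers),
    nest = arc(0, pi / 2),
    max_speed = pi / 9,
    trial_steps = 100L
  ), class = "world_spec")
}

#' Floor sensor for food detection
#'
#' The sender's floor sensor switches from 0 to 1 when the sender stands on
#' the foraging site that currently contains food. It stays 0 on every other
#' site and everywhere else (including the nest).
#'
#' @param sender_pos Sender position(s), radians.
#' @param food_site Index of the food-bearing site, 1 to 5.
#' @param world A [world_spec()].
#' @return Integer vector of 0/1 values.
#' @export
food_sensor <- function(sender_pos, food_site, world = world_spec()) {
  if (!is.numeric(food_site) || length(food_site) != 1 ||
      is.na(food_site) || food_site < 1 || food_site > 5 ||
      food_site != round(food_site)) {
    stop("`food_site` must be a single site index in 1..5", call. = FALSE)
  }
  as.integer(in_arc(sender_pos, world$sites[[food_site]]))
}

#' Advance an agent one step along the circle
#'
#' @param position Current position(s), radians.
#' @param speed Angular speed in radians per step; must lie in
#'   \code{[0, max_speed]}.
#' @param direction +1 (counterclockwise) or -1 (clockwise).
#' @param world A [world_spec()] providing the speed bound.
#' @return New normalized position(s).
#' @export
step_position <- function(position, speed, direction, world = world_spec()) {
  if (any(speed < 0 | speed > world$max_speed + 1e-12)) {
    stop("`speed` must lie in [0, max_speed]", call. = FALSE)
  }
  if (!all(direction %in% c(-1, 1))) {
    stop("`direction` must be -1 or +1", call. = FALSE)
  }
  normalize_angle(position + direction * speed)
}

#' Nest-gated signal transmission
#'
#' The receiver perceives the sender's emitted amplitude only while both
#' agents are simultaneously inside the nest; outside of it the perceived
#' signal is zero. The gating is multiplicative: perceived never exceeds
#' emitted.
#'
#' @param sender_pos,receiver_pos Agent positions, radians.
#' @param emitted Emitted amplitude in \code{[0, 1]}.
#' @param world A [world_spec()].
#' @return Perceived amplitude(s) in \code{[0, 1]}.
#' @export
perceived_signal <- function(sender_pos, receiver_pos, emitted,
                             world = world_spec()) {
  stopifnot(all(emitted >= 0 & emitted <= 1))
  ifelse(in_arc(sender_pos, world$nest) & in_arc(receiver_pos, world$nest),
         emitted, 0)
}
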