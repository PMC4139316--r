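#' Net energetic value of a foraging trip
#'
#' The profitability signal behind both the dance and the next-day return
#' decision: gross load energy minus the round-trip flight cost and the
#' handling costs (on-patch feeding at flight metabolic rate, in-nest
#' unloading at resting rate),
#' \deqn{q_t = V q E_{mol} - \frac{2d}{v w} c_{move} -
#'   (t_{patch} c_{move} + t_{nest} c_{rest})}
#' with distance \eqn{d} in metres and cell width \eqn{w}.  Strictly
#' increasing in quality, strictly decreasing in distance.
#'
#' @param quality nectar quality, mol/l (>= 0); vectorised.
#' @param distance_m nest-to-patch distance in metres (>= 0); vectorised.
#' @param params a \code{\link{sim_params}} object.
#' @return Net trip value in joules.
#' @export
effective_value <- function(quality, distance_m, params) {
  if (any(quality < 0)) stop("quality must be >= 0")
  if (any(distance_m < 0)) stop("distance_m must be >= 0")
  c_move <- params$c_rest * params$c_move_factor
  flight <- 2 * distance_m / (params$v * params$cell_width_m) * c_move
  handling <- params$t_patch_mean * c_move + params$t_nest * params$c_rest
  trip_value(quality, params) - flight - handling
}

#' Probability of dancing for a food source
#'
#' Logistic in the net trip value:
#' \deqn{p_d = \frac{1}{1 + e^{-(q_t - \mathrm{mid})/\mathrm{slope}}}}
#' so dancing rises with nectar quality and falls with distance, the
#' quality-response sigmoid shifting right as foraging distance grows.  The
#' midpoint and slope are calibration parameters
#' (\code{dance_midpoint}, \code{dance_slope}; see \code{\link{sim_params}}).
#'
#' @inheritParams effective_value
#' @return Dance probability in [0, 1].
#' @export
dance_probability <- function(quality, distance_m, params) {
  z <- (effective_value(quality, distance_m, params) - params$dance_midpoint) /
    params$dance_slope
  stats::plogis(z)
}

#' Dance suppression by forager influx
#'
#' When many foragers return at once, unloading bees dance less.  The
#' multiplier on the dance probability falls linearly from 1 at zero recent
#' returns to \code{influx_floor} at 20, and stays flat beyond.
#'
#' @param n_recent_returns count of foragers returned within the trailing
#'   \code{influx_window} steps (>= 0); vectorised.
#' @param params a \code{\link{sim_params}} object.
#' @return Multiplier in [\code{influx_floor}, 1].
#' @export
influx_factor <- function(n_recent_returns, params) {
  if (any(n_recent_returns < 0)) stop("n_recent_returns must be >= 0")
  k <- pmin(n_recent_returns, 20)
  1 - (1 - params$influx_floor) * k / 20
}

#' Probability an experienced recruit returns to its site the next day
#'
#' The abandonment decision mirrors the dance decision: the return curve is
#' the dance curve shifted up by \code{return_shift} (default 0.30) and
#' clamped at 1, so a source danced for 50% of the time is revisited with
#' probability 0.8.  Abandonment probability is the complement.
#'
#' @inheritParams effective_value
#' @return Return probability in [0, 1].
#' @export
return_probability <- function(quality, distance_m, params) {
  pmin(1, dance_probability(quality, distance_m, params) +
         params$return_shift)
}
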