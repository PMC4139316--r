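#' Levy-flight leg lengths
#'
#' Search legs follow the inverse-CDF power law
#' \eqn{d = (1 - a)^{1/(1 - \mu)}} with \eqn{a \sim U[0,1)}: a heavy-tailed
#' distribution with minimum leg 1 cell width and tail exponent
#' \code{mu_levy}.  Supply \code{a} for the deterministic transform, or
#' \code{n} to draw from R's random stream (the simulation engine uses its
#' own seeded stream internally).
#'
#' @param n number of draws (ignored when \code{a} is given).
#' @param mu_levy tail exponent, must be > 1.
#' @param a optional uniform variates in [0, 1).
#' @return Numeric vector of leg lengths in cell widths.
#' @export
draw_levy_length <- function(n = 1, mu_levy = 2.4, a = NULL) {
  if (mu_levy <= 1) stop("mu_levy must be > 1")
  if (is.null(a)) a <- stats::runif(n)
  if (any(a < 0 | a >= 1)) stop("a must lie in [0, 1)")
  (1 - a)^(1 / (1 - mu_levy))
}

#' Energetic cost of one time step
#'
#' Agents resting in the nest (idle, waiting for a dance, unloading/dancing)
#' spend \code{c_rest} joules per 10-s step; airborne or on-patch agents
#' spend \code{c_move_factor} times that.
#'
#' @param state character: one of \code{"idle"}, \code{"waiting"},
#'   \code{"unloading"}, \code{"dancing"} (resting) or \code{"scouting"},
#'   \code{"flying"}, \code{"feeding"}, \code{"returning"} (moving);
#'   vectorised.
#' @param params a \code{\link{sim_params}} object.
#' @return Cost in joules per step.
#' @export
step_cost <- function(state, params) {
  resting <- c("idle", "waiting", "unloading", "dancing")
  moving <- c("scouting", "flying", "feeding", "returning")
  if (!all(state %in% c(resting, moving)))
    stop("unknown agent state: ",
         paste(setdiff(state, c(resting, moving)), collapse = ", "))
  ifelse(state %in% resting, params$c_rest,
         params$c_rest * params$c_move_factor)
}

#' Energy delivered by one foraging trip
#'
#' A full load is \code{load_volume_ul} microlitres of nectar at
#' concentration \code{quality} mol/l, worth \code{e_mol} joules per mol of
#' sugar: \eqn{E = V \times 10^{-6} \times q \times E_{mol}}.  At defaults a
#' 1 mol/l load delivers 282.25 J.
#'
#' @param quality nectar quality in mol/l (>= 0); vectorised.
#' @param params a \code{\link{sim_params}} object.
#' @return Delivered energy in joules.
#' @export
trip_value <- function(quality, params) {
  if (any(quality < 0)) stop("quality must be >= 0")
  params$load_volume_ul * 1e-6 * quality * params$e_mol
}
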