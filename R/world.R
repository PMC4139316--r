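#' Initialise the forage landscape
#'
#' Builds the square grid world around the nest: every non-nest cell becomes
#' a forage patch with probability \code{d_patch}, with nectar quality drawn
#' from a truncated normal (mean \code{q_mean}, sd \code{q_sd}, redrawn while
#' below 0.05 mol/l) and age uniform on 1..\code{a_max} days.  The nest cell
#' (the grid centre) never carries forage.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param seed integer seed for the world's private random stream.
#' @return A \code{forage_world}: list with logical matrix \code{is_forage},
#'   numeric \code{quality}, integer \code{age} (all side x side, side =
#'   \code{2 * grid_half_extent + 1}) and \code{half_extent}.
#' @export
init_world <- function(params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  w <- cpp_init_world(params, as.integer(seed))
  class(w) <- c("forage_world", "list")
  w
}

#' Advance the landscape by one day
#'
#' Patch ages increment; patches older than \code{a_max} disappear; empty
#' cells sprout new patches (age 1, fresh quality draw) with the per-day
#' birth probability of the configured mode: \code{d_patch} in
#' \code{"literal"} mode, or \code{d_patch / (a_max * (1 - d_patch))} in
#' \code{"stationary"} mode, which balances births against the 1/\code{a_max}
#' per-day death rate so long-run occupancy stays near \code{d_patch}.
#'
#' @inheritParams init_world
#' @param world a \code{forage_world}.
#' @return The updated \code{forage_world}.
#' @export
daily_turnover <- function(world, params, seed = 1L) {
  stopifnot(inherits(world, "forage_world"), inherits(params, "sim_params"))
  w <- cpp_daily_turnover(world, params, as.integer(seed))
  class(w) <- c("forage_world", "list")
  w
}

#' Is foraging possible at this time of day?
#'
#' The day runs from 06:00 in steps of 10 s; flight conditions are suitable
#' from 06:23 (step 138) to 17:37 (step 4182), with no seasonal change.
#'
#' @param step_of_day integer step index in \code{[0, t_day)}; vectorised.
#' @param params a \code{\link{sim_params}} object.
#' @return Logical vector: \code{TRUE} where the foraging window is open.
#' @export
foraging_allowed <- function(step_of_day, params) {
  stopifnot(inherits(params, "sim_params"))
  if (any(step_of_day < 0 | step_of_day >= params$t_day))
    stop("step_of_day outside [0, t_day)")
  step_of_day >= params$forage_open & step_of_day <= params$forage_close
}

#' Map continuous positions to grid cells
#'
#' Cells are unit squares centred on integer coordinates (the nest at the
#' origin), half-open on their upper edges, so \code{(0.49, 0)} is the nest
#' cell and \code{(0.51, 0)} belongs to cell (1, 0).
#'
#' @param x,y numeric coordinates in cell widths relative to the nest.
#' @param half_extent world half-extent in cells (default 100).
#' @return Integer matrix with columns \code{cx}, \code{cy}.
#' @export
cell_of <- function(x, y, half_extent = 100L) {
  lim <- half_extent + 0.5
  if (any(abs(x) > lim | abs(y) > lim))
    stop("position outside the world bounds")
  cbind(cx = as.integer(floor(x + 0.5)), cy = as.integer(floor(y + 0.5)))
}

#' Write a snapshot of the landscape state
#'
#' Debug helper: one CSV row per cell with coordinates, forage flag, quality
#' and age.
#'
#' @param world a \code{forage_world}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_world_snapshot <- function(world, path) {
  h <- world$half_extent
  co <- seq(-h, h)
  df <- data.frame(
    cell_x = rep(co, times = length(co)),
    cell_y = rep(co, each = length(co)),
    is_forage = as.vector(world$is_forage),
    quality = as.vector(world$quality),
    age = as.vector(world$age)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.forage_world <- function(x, ...) {
  n <- length(x$is_forage)
  cat("<forage_world>", 2 * x$half_extent + 1, "x", 2 * x$half_extent + 1,
      "cells;", sum(x$is_forage), "forage patches (",
      signif(sum(x$is_forage) / (n - 1), 3), "occupancy )\n")
  invisible(x)
}
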