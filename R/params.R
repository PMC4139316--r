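#' Model parameters for the colony foraging simulation
#'
#' Constructs the full parameter set of the agent-based model: colony
#' composition, the daily clock, the stochastic forage landscape, flight and
#' energetics constants, the dance/abandonment calibration, and replication
#' settings.  Defaults are the published table of model defaults; every value
#' can be overridden by name.
#'
#' Units: time in 10-s steps (one day = \code{t_day} = 8640 steps), distance
#' internally in cell widths (one cell = \code{cell_width_m} = 100 m),
#' energies in joules, nectar quality in mol/l sugar.
#'
#' Two calibration constants of the dance curve, \code{dance_midpoint} (J)
#' and \code{dance_slope} (J), default to \code{NULL} and are then derived at
#' validation time: the midpoint is the net trip value of a 1.3 mol/l source
#' at 2 km and the slope a quarter of the midpoint, so that only
#' clearly above-average sources are danced for reliably.  See
#' \code{\link{dance_probability}} and the methods vignette for how this
#' calibration (together with \code{p_detect}) was fixed against the
#' medium-density baseline.
#'
#' @param ... named parameter overrides, e.g. \code{sim_params(d_patch = 0.01)}.
#' @return A validated object of class \code{sim_params} (a named list).
#' @seealso \code{\link{validate_params}}, \code{\link{read_params}}
#' @examples
#' p <- sim_params()
#' p$p_exit
#' low <- sim_params(d_patch = 0.01)
#' @export
sim_params <- function(...) {
  p <- default_params()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(p)
}

default_params <- function() {
  list(
    # colony composition
    n_scouts = 30L,
    n_recruits = 270L,
    # clock
    t_day = 8640L,            # 10-s steps per day
    t_init = 3L,              # acclimatization days (always SI)
    n_exp_days = 48L,         # experimental days after acclimatization
    t_switch = "3",           # cycle length in days ("none", "2", "3", "12")
    # leaving the nest
    p_exit = 0.815,           # per-step exit probability, motivated foragers
    p_rs = 0.00009,           # per-step probability an idle recruit scouts
    # landscape
    d_patch = 0.05,           # target patch density
    a_max = 14L,              # patch longevity, days
    patch_birth_mode = "stationary",
    grid_half_extent = 100L,  # cells from nest to edge (201 x 201 world)
    cell_width_m = 100,
    # trips
    y_patch = 50,             # nectar load per trip, mg
    t_patch_mean = 180,       # on-patch handling time, steps
    t_patch_sd = 60,
    t_nest = 6L,              # unloading steps in the nest
    q_mean = 1.0,             # nectar quality, mol/l
    q_sd = 0.2,
    v = 0.7,                  # flight speed, cell widths per step
    mu_levy = 2.4,            # Levy-flight tail exponent
    # energetics
    c_rest = 0.04861,         # J per resting step
    c_move_factor = 9,        # flight/feeding cost multiplier
    m = 0.000007,             # per-step mortality
    e_mol = 5645000,          # J per mol sugar
    c_recruit = 325,          # recruit search penalty, J
    load_volume_ul = 50,      # nectar volume per load (1 mg ~ 1 ul)
    p_detect = 0.4,           # chance a leg-end scan notices forage
    # communication
    n_dance = 1L,             # followers per dance
    p_dance = 0.25,           # per-dance recruitment success (SI)
    dance_midpoint = NULL,    # J; derived when NULL
    dance_slope = NULL,       # J; derived when NULL
    return_shift = 0.30,      # next-day return prob above dance prob
    influx_window = 60L,      # steps over which returns are counted
    influx_floor = 0.0,       # dance multiplier at >= 20 recent returns
    # foraging window (06:23-17:37 at 10 s/step, day start 06:00)
    forage_open = 138L,
    forage_close = 4182L,
    persistent_recruits = TRUE,
    # replication
    n_runs = 12L,
    base_seed = 20140820L
  )
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter set and either returns the
#' (possibly completed) set or stops with a message listing all violations.
#' Derives \code{dance_midpoint}/\code{dance_slope} when unset.
#'
#' @param p a named list as produced by \code{\link{sim_params}}.
#' @return The validated \code{sim_params} object.
#' @export
validate_params <- function(p) {
  errs <- character()
  need <- setdiff(names(default_params()), names(p))
  if (length(need))
    stop("missing parameter(s): ", paste(need, collapse = ", "))

  chk_prob <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      errs <<- c(errs, sprintf("%s must be a probability in [0, 1] (got %s)",
                               nm, format(p[[nm]])))
  }
  chk_nonneg <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      errs <<- c(errs, sprintf("%s must be >= 0 (got %s)", nm, format(v)))
  }
  chk_count <- function(nm, min = 0) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min ||
        v != as.integer(v))
      errs <<- c(errs, sprintf("%s must be an integer >= %d (got %s)",
                               nm, min, format(v)))
  }

  for (nm in c("p_exit", "p_rs", "d_patch", "m", "p_dance", "p_detect",
               "influx_floor", "return_shift"))
    chk_prob(nm)
  for (nm in c("y_patch", "t_patch_mean", "t_patch_sd", "q_mean", "q_sd",
               "v", "c_rest", "c_move_factor", "e_mol", "c_recruit",
               "load_volume_ul", "cell_width_m"))
    chk_nonneg(nm)
  for (nm in c("n_scouts", "n_recruits", "t_nest", "n_dance",
               "influx_window", "n_exp_days"))
    chk_count(nm, 0)
  for (nm in c("t_day", "t_init", "a_max", "grid_half_extent", "n_runs"))
    chk_count(nm, 1)

  if (!is.numeric(p$mu_levy) || p$mu_levy <= 1)
    errs <- c(errs,
              "mu_levy must be > 1 (the inverse-CDF exponent 1/(1 - mu_levy) diverges at 1)")
  if (!(is.character(p$t_switch) && p$t_switch %in%
        c("none", "2", "3", "12")) &&
      !(is.numeric(p$t_switch) && p$t_switch >= 1))
    errs <- c(errs, "t_switch must be \"none\" or a cycle length in days")
  if (!p$patch_birth_mode %in% c("stationary", "literal"))
    errs <- c(errs, "patch_birth_mode must be \"stationary\" or \"literal\"")
  if (!is.logical(p$persistent_recruits) || length(p$persistent_recruits) != 1)
    errs <- c(errs, "persistent_recruits must be TRUE or FALSE")
  ok_steps <- is.numeric(p$forage_open) && is.numeric(p$forage_close) &&
    is.numeric(p$t_day)
  if (ok_steps && !(p$forage_open < p$forage_close &&
                    p$forage_close < p$t_day))
    errs <- c(errs, "need forage_open < forage_close < t_day")

  if (length(errs))
    stop("invalid parameters:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)

  # integer storage for whole-number fields
  for (nm in c("n_scouts", "n_recruits", "t_day", "t_init", "n_exp_days",
               "a_max", "t_nest", "n_dance", "influx_window",
               "grid_half_extent", "forage_open", "forage_close",
               "n_runs", "base_seed"))
    p[[nm]] <- as.integer(p[[nm]])

  # derive the dance-curve calibration if left open
  if (is.null(p$dance_midpoint)) {
    p$dance_midpoint <- effective_value(1.3, 2000, within_validate(p))
  }
  if (is.null(p$dance_slope)) {
    p$dance_slope <- 0.25 * p$dance_midpoint
  }
  if (!is.numeric(p$dance_slope) || p$dance_slope <= 0)
    stop("invalid parameters:\n  - dance_slope must be > 0", call. = FALSE)

  class(p) <- c("sim_params", "list")
  p
}

# minimal stamped copy so effective_value() can be used mid-validation
within_validate <- function(p) {
  class(p) <- c("sim_params", "list")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> colony", x$n_scouts, "scouts +", x$n_recruits,
      "recruits;", x$t_init + x$n_exp_days, "days of", x$t_day, "steps\n")
  cat("  landscape: d_patch =", x$d_patch, ", a_max =", x$a_max,
      "days,", paste0(2 * x$grid_half_extent + 1, "^2"), "cells,",
      x$patch_birth_mode, "births\n")
  cat("  dance curve: midpoint =", signif(x$dance_midpoint, 5),
      "J, slope =", signif(x$dance_slope, 5),
      "J, return shift =", x$return_shift, "\n")
  invisible(x)
}

#' Read / write a parameter configuration file
#'
#' Flat key-value configuration in JSON or YAML (chosen by file extension).
#' Keys not in the parameter set are rejected; missing keys take their
#' defaults.  \code{write_params} followed by \code{read_params} round-trips
#' the full set.
#'
#' @param path file path ending in \code{.json}, \code{.yaml} or \code{.yml}.
#' @return \code{read_params}: a validated \code{sim_params};
#'   \code{write_params}: the path, invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- switch(file_ext(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml: ", path)
  )
  if (!is.list(raw)) stop("config must be a flat key-value mapping")
  do.call(sim_params, raw)
}

#' @param params a \code{sim_params} object.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  x <- unclass(params)
  switch(file_ext(path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(x, path, precision = 15L),
    stop("config must be .json, .yaml or .yml: ", path)
  )
  invisible(path)
}

file_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

n_days_total <- function(params) params$t_init + params$n_exp_days
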