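#' Relative benefit of spatial information
#'
#' Percentage gain of the SI condition over NI:
#' \code{100 * (mean(si) - mean(ni)) / mean(ni)}, computed from per-run
#' mean daily gains.
#'
#' @param si_gains,ni_gains per-run mean daily net gains (J/day) of the SI
#'   and NI replicate sets.
#' @return Percent benefit; \code{NA} with a warning when the NI mean is
#'   not positive (the ratio is then undefined).
#' @export
relative_benefit <- function(si_gains, ni_gains) {
  if (!length(si_gains) || !length(ni_gains))
    stop("both replicate sets must be non-empty")
  ni <- mean(ni_gains)
  if (ni <= 0) {
    warning("NI mean gain is not positive; relative benefit undefined")
    return(NA_real_)
  }
  100 * (mean(si_gains) - ni) / ni
}

#' Mean and standard error over replicate runs
#'
#' @param x per-run values.
#' @return List with \code{mean}, \code{se} (= sd / sqrt(n)) and \code{n}.
#' @export
replicate_summary <- function(x) {
  n <- length(x)
  list(mean = mean(x), se = stats::sd(x) / sqrt(n), n = n)
}

#' Per-capita foraging efficiency by role
#'
#' Net energy collected per forager-day for one role: role deliveries minus
#' the role's individual costs (step costs, plus recruitment penalties for
#' recruits), divided by agent-days, with acclimatization days excluded.
#' \code{gross = TRUE} skips the cost side.
#'
#' @param days day table from \code{\link{run_simulation}} or
#'   \code{\link{replicate_runs}}.
#' @param params the \code{\link{sim_params}} used to produce it.
#' @param role \code{"scout"} or \code{"recruit"}.
#' @param gross report gross deliveries per agent-day instead of net.
#' @return Joules per forager per day.
#' @export
per_capita_efficiency <- function(days, params, role = c("scout", "recruit"),
                                  gross = FALSE) {
  role <- match.arg(role)
  d <- days[!days$acclim, , drop = FALSE]
  n_role <- if (role == "scout") params$n_scouts else params$n_recruits
  agent_days <- n_role * nrow(d)
  if (agent_days == 0) stop("no agent-days for role ", role)
  deliv <- sum(d[[paste0("deliv_", role)]])
  if (gross) return(deliv / agent_days)
  costs <- sum(d[[paste0("cost_", role)]]) +
    if (role == "recruit") sum(d$penalties) else 0
  (deliv - costs) / agent_days
}

#' Poisson summary of site persistency
#'
#' Fits a Poisson distribution to the observed per-recruit site tenures
#' (consecutive days exploiting one patch) by maximum likelihood.  The MLE
#' of the mean is the sample mean with standard error
#' \code{sqrt(mean / n)}.
#'
#' @param tenure_days integer vector of completed tenure spells, each >= 1
#'   day.
#' @return List with \code{mean}, \code{se} and \code{n}.
#' @export
persistency_poisson <- function(tenure_days) {
  if (!length(tenure_days)) stop("no tenure spells supplied")
  if (any(tenure_days < 1)) stop("tenure spells must be >= 1 day")
  n <- length(tenure_days)
  m <- mean(tenure_days)
  list(mean = m, se = sqrt(m / n), n = n)
}

#' Carry-over profile across switch blocks
#'
#' Mean daily net gain by condition and day-position within the condition
#' block, pooled over runs (acclimatization excluded).  In switch designs
#' with persistent recruits, the first NI day of a block inherits foragers
#' recruited during the preceding SI block, so its mean exceeds later NI
#' days; this table exposes that contamination.
#'
#' @param days stacked day table from \code{\link{replicate_runs}}.
#' @return Data frame with \code{condition}, \code{position} (day within
#'   block, 1-based), \code{mean_gain}, \code{se} and \code{n_days}.
#' @export
carryover_profile <- function(days) {
  d <- days[!days$acclim, , drop = FALSE]
  if (!nrow(d)) stop("no experimental days")
  if (is.null(d$run)) d$run <- 1L
  d <- d[order(d$run, d$day), ]
  pos <- unlist(lapply(split(d$condition, d$run), function(cond) {
    r <- rle(cond)
    sequence(r$lengths)
  }), use.names = FALSE)
  d$position <- pos
  agg <- aggregate(net_gain ~ condition + position, data = d,
                   FUN = function(x) c(mean = mean(x),
                                       se = stats::sd(x) / sqrt(length(x)),
                                       n = length(x)))
  out <- data.frame(condition = agg$condition, position = agg$position,
                    mean_gain = agg$net_gain[, "mean"],
                    se = agg$net_gain[, "se"],
                    n_days = agg$net_gain[, "n"])
  out[order(out$condition, out$position), ]
}

#' Preset experiment suites
#'
#' The parameter/design grids of the study's simulation experiments:
#' \describe{
#'   \item{experiment1}{food density \code{d_patch} in \{0.1, 0.05, 0.01\}
#'     crossed with designs \{no-switch, 2-, 3-, 12-day cycles\} (12 sets).}
#'   \item{experiment2}{medium density, patch longevity \code{a_max} in
#'     \{1, 7, 14, 28\} days crossed with the same designs (16 sets).}
#'   \item{no_cost}{recruitment made certain and free (\code{p_dance = 1},
#'     \code{c_recruit = 0}) at \code{a_max} in \{7, 21\}, no-switch and
#'     2-day designs (4 sets).}
#'   \item{sensitivity}{one-factor sweeps around defaults: colony size
#'     \{300, 600, 1200\} at a 1:9 scout:recruit ratio, Levy exponent
#'     \{2, 3, 4\}, exit probability \{0.01, 0.1, 0.5, 0.8\}, recruit cost
#'     \{0, 325\} and recruit persistence on/off, each under the default
#'     3-day switch design.}
#' }
#'
#' @param name preset name.
#' @param params base parameters the grid is applied to.
#' @return List of entries, each with \code{params}, \code{cycle} and
#'   \code{label}.
#' @export
preset_experiments <- function(name = c("experiment1", "experiment2",
                                        "no_cost", "sensitivity"),
                               params = sim_params()) {
  name <- match.arg(name)
  entry <- function(label, cycle, ...) {
    ov <- list(...)
    p <- params
    p[names(ov)] <- ov
    list(params = validate_params(unclass(p)), cycle = cycle, label = label)
  }
  cycles <- c("none", "2", "3", "12")
  switch(name,
    experiment1 = {
      grid <- expand.grid(d = c(0.1, 0.05, 0.01), cy = cycles,
                          stringsAsFactors = FALSE)
      Map(function(d, cy)
            entry(sprintf("density%.2f-%s", d, cy), cy, d_patch = d),
          grid$d, grid$cy)
    },
    experiment2 = {
      grid <- expand.grid(a = c(1L, 7L, 14L, 28L), cy = cycles,
                          stringsAsFactors = FALSE)
      Map(function(a, cy)
            entry(sprintf("longevity%02d-%s", a, cy), cy, a_max = a),
          grid$a, grid$cy)
    },
    no_cost = {
      grid <- expand.grid(a = c(7L, 21L), cy = c("none", "2"),
                          stringsAsFactors = FALSE)
      Map(function(a, cy)
            entry(sprintf("nocost%02d-%s", a, cy), cy,
                  a_max = a, p_dance = 1, c_recruit = 0),
          grid$a, grid$cy)
    },
    sensitivity = c(
      lapply(c(300L, 600L, 1200L), function(n)
        entry(sprintf("colony%d", n), "3",
              n_scouts = n %/% 10L, n_recruits = n - n %/% 10L)),
      lapply(c(2, 3, 4), function(mu)
        entry(sprintf("mu%.0f", mu), "3", mu_levy = mu)),
      lapply(c(0.01, 0.1, 0.5, 0.8), function(pe)
        entry(sprintf("pexit%.2f", pe), "3", p_exit = pe)),
      lapply(c(0, 325), function(cc)
        entry(sprintf("crecruit%d", cc), "3", c_recruit = cc)),
      lapply(c(TRUE, FALSE), function(pr)
        entry(sprintf("persistence-%s", if (pr) "on" else "off"), "3",
              persistent_recruits = pr))
    )
  )
}
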