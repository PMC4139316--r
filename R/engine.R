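#' Build a daily SI/NI condition schedule
#'
#' The first \code{t_init} days are always SI (the acclimatization phase).
#' Afterwards the colony either stays in its allocated condition for the
#' remaining \code{n_exp_days} (\code{cycle = "none"}) or alternates between
#' SI and NI in blocks of \code{cycle} days, beginning with \code{start}.
#'
#' @param cycle \code{"none"} or a block length in days (\code{"2"},
#'   \code{"3"}, \code{"12"}, or any positive integer).
#' @param start condition of the first experimental block, \code{"SI"} or
#'   \code{"NI"}.
#' @param params a \code{\link{sim_params}} object.
#' @return Character vector of length \code{t_init + n_exp_days} with
#'   entries \code{"SI"} / \code{"NI"}.
#' @export
condition_schedule <- function(cycle = "none", start = c("SI", "NI"),
                               params = sim_params()) {
  start <- match.arg(start)
  n <- params$n_exp_days
  if (identical(cycle, "none")) {
    exp_days <- rep(start, n)
  } else {
    len <- suppressWarnings(as.integer(cycle))
    if (is.na(len) || len < 1)
      stop("cycle must be \"none\" or a positive number of days")
    blocks <- rep(c(start, setdiff(c("SI", "NI"), start)),
                  length.out = ceiling(n / len))
    exp_days <- rep(blocks, each = len)[seq_len(n)]
  }
  c(rep("SI", params$t_init), exp_days)
}

#' Describe one replicate set
#'
#' @param cycle schedule cycle, as in \code{\link{condition_schedule}}.
#' @param start allocated condition of the first block (for no-switch
#'   designs, the condition of the whole run).
#' @param n_runs number of replicate runs.
#' @param base_seed seed of the first run; run \code{i} uses
#'   \code{base_seed + i - 1}.
#' @param label free-text label carried into outputs.
#' @param params a \code{\link{sim_params}} object.
#' @return An \code{experiment_plan} object.
#' @export
experiment_plan <- function(cycle = "none", start = "SI",
                            n_runs = NULL, base_seed = NULL,
                            label = NULL, params = sim_params()) {
  plan <- list(
    cycle = cycle,
    start = match.arg(start, c("SI", "NI")),
    n_runs = if (is.null(n_runs)) params$n_runs else as.integer(n_runs),
    base_seed = if (is.null(base_seed)) params$base_seed
                else as.integer(base_seed),
    label = if (is.null(label)) {
      if (identical(cycle, "none")) paste0("no-switch-", start)
      else paste0("cycle", cycle)
    } else label
  )
  stopifnot(plan$n_runs >= 1)
  class(plan) <- c("experiment_plan", "list")
  plan
}

#' Run one simulation
#'
#' Simulates the colony through the full day schedule: each day the
#' landscape turns over, experienced recruits decide whether to keep their
#' site, and the colony then lives through \code{t_day} 10-s steps of
#' exits, Levy-flight search or direct site flights, feeding, homing,
#' unloading with dance decisions (oriented under SI, disoriented under
#' NI), and mortality with in-nest replacement.  Identical inputs and seed
#' give identical output.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param schedule character vector of daily conditions from
#'   \code{\link{condition_schedule}}; defaults to the no-switch SI design.
#' @param seed integer seed of the run's private random stream.
#' @return A \code{sim_run}: list with \code{days} (one row per day: net
#'   energy gain in J, median completed-trip distance in m, trips and
#'   deliveries by role, step costs by role, recruitment penalties, deaths,
#'   recruits holding sites, live forage cells), \code{tenures} (completed
#'   per-recruit site tenures in days) and \code{n_agents}.
#' @export
run_simulation <- function(params, schedule = NULL, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(schedule))
    schedule <- condition_schedule("none", "SI", params)
  if (!all(schedule %in% c("SI", "NI")))
    stop("schedule entries must be \"SI\" or \"NI\"")
  res <- cpp_run_simulation(params, as.integer(schedule == "SI"),
                            as.double(seed))
  days <- res$days
  days$condition <- ifelse(days$condition == 1, "SI", "NI")
  days$acclim <- days$day <= params$t_init
  out <- list(days = days, tenures = res$tenures,
              n_agents = res$n_agents, seed = as.integer(seed))
  class(out) <- c("sim_run", "list")
  out
}

#' Run a replicate set
#'
#' Runs \code{n_runs} independent simulations with seeds
#' \code{base_seed + 0:(n_runs-1)}.  For switch designs, runs are split
#' evenly between SI-first and NI-first schedules (odd counts warn and
#' floor the split); no-switch runs all use the plan's allocated condition.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param plan an \code{\link{experiment_plan}}.
#' @return List with \code{days} (stacked day table with \code{run} and
#'   \code{start} columns) and \code{tenures} (data frame \code{run},
#'   \code{tenure}).
#' @export
replicate_runs <- function(params, plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  n <- plan$n_runs
  starts <- rep(plan$start, n)
  if (!identical(plan$cycle, "none")) {
    n_first <- n %/% 2L
    if (n %% 2L != 0L)
      warning("odd n_runs with a switch design; flooring the split")
    other <- setdiff(c("SI", "NI"), plan$start)
    starts <- c(rep(plan$start, n - n_first), rep(other, n_first))
  }
  day_list <- vector("list", n)
  ten_list <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- condition_schedule(plan$cycle, starts[i], params)
    r <- run_simulation(params, sched, plan$base_seed + i - 1L)
    d <- r$days
    d$run <- i
    d$start <- starts[i]
    day_list[[i]] <- d
    if (length(r$tenures))
      ten_list[[i]] <- data.frame(run = i, tenure = r$tenures)
  }
  list(days = do.call(rbind, day_list),
       tenures = if (length(ten_list <- Filter(Negate(is.null), ten_list)))
         do.call(rbind, ten_list)
       else data.frame(run = integer(), tenure = integer()),
       plan = plan)
}

#' Per-run mean daily net gain
#'
#' Mean daily net energy gain per run over experimental days
#' (acclimatization excluded), optionally restricted to days in one
#' condition.
#'
#' @param days stacked day table from \code{\link{replicate_runs}}.
#' @param condition optional \code{"SI"} or \code{"NI"} day filter.
#' @return Named numeric vector of per-run means (J/day).
#' @export
run_means <- function(days, condition = NULL) {
  d <- days[!days$acclim, , drop = FALSE]
  if (!is.null(condition)) d <- d[d$condition == condition, , drop = FALSE]
  if (!nrow(d)) stop("no matching experimental days")
  tapply(d$net_gain, d$run, mean)
}

#' SI-vs-NI contrast for a no-switch design
#'
#' Runs an SI-only and an NI-only replicate set (disjoint seed blocks) and
#' summarises the relative benefit of spatial information.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param n_runs replicates per condition.
#' @param base_seed first seed; the NI set is offset by \code{seed_gap}.
#' @param seed_gap seed offset between the SI and NI sets.
#' @return List with per-run means, the two replicate sets and
#'   \code{benefit_pct} = 100 (mean SI - mean NI) / mean NI.
#' @export
no_switch_benefit <- function(params, n_runs = params$n_runs,
                              base_seed = params$base_seed,
                              seed_gap = 100000L) {
  si <- replicate_runs(params, experiment_plan("none", "SI", n_runs,
                                               base_seed, params = params))
  ni <- replicate_runs(params, experiment_plan("none", "NI", n_runs,
                                               base_seed + seed_gap,
                                               params = params))
  si_m <- run_means(si$days)
  ni_m <- run_means(ni$days)
  list(benefit_pct = relative_benefit(si_m, ni_m),
       si_run_means = si_m, ni_run_means = ni_m,
       si = si, ni = ni)
}

#' Apparent SI-vs-NI contrast inside a switch design
#'
#' Runs one switching replicate set (half SI-first, half NI-first) and
#' contrasts mean daily gain on SI-condition days against NI-condition
#' days, as a switch experiment would measure it.
#'
#' @inheritParams no_switch_benefit
#' @param cycle block length in days (\code{"2"}, \code{"3"}, \code{"12"}).
#' @return List with per-run SI-day and NI-day means, the replicate set and
#'   the apparent \code{benefit_pct}.
#' @export
switch_benefit <- function(params, cycle, n_runs = params$n_runs,
                           base_seed = params$base_seed) {
  rr <- replicate_runs(params, experiment_plan(cycle, "SI", n_runs,
                                               base_seed, params = params))
  si_m <- run_means(rr$days, "SI")
  ni_m <- run_means(rr$days, "NI")
  list(benefit_pct = relative_benefit(si_m, ni_m),
       si_run_means = si_m, ni_run_means = ni_m, runs = rr)
}

#' @export
print.sim_run <- function(x, ...) {
  d <- x$days[!x$days$acclim, ]
  cat("<sim_run>", nrow(x$days), "days,", x$n_agents, "agents, seed",
      x$seed, "\n  mean experimental net gain:",
      round(mean(d$net_gain)), "J/day; median trip distance:",
      round(stats::median(d$median_trip_m, na.rm = TRUE)), "m\n")
  invisible(x)
}
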