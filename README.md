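# waggleforage

An agent-based simulation of honeybee colony nectar foraging, built to ask
a methodological question in behavioural ecology: **how much does the
spatial information in the waggle dance actually help a colony, and why do
crossover field experiments so often fail to see it?**

Foragers in the model are scouts (independent Lévy-flight searchers) and
recruits (followers of dances). Under **SI** (spatial information,
oriented dances) a dance transmits the advertised patch's location to a
follower; under **NI** (disoriented dances) it merely arouses one recruit
to go scouting. Recruits are site-faithful: each morning an experienced
recruit returns to yesterday's patch with probability

    p_return(q, d) = min(1, p_d(q, d) + 0.30),
    p_d(q, d)      = logistic((q_t(q, d) - midpoint) / slope),

where `q_t` is the net energetic value of a foraging trip to a source of
quality `q` (mol/l sugar) at distance `d` (J gross load minus round-trip
flight and handling costs). Because recruitment keeps paying off for days,
repeatedly switching one colony between SI and NI books income earned from
SI-era recruitment under NI days — the carry-over effect that biases
crossover designs toward "no benefit".

The package provides:

* the full parameterised simulator (`sim_params()`, `run_simulation()`),
  with a fast C++ core and bitwise-reproducible seeded runs;
* the stochastic forage landscape (patch density, quality, bounded
  lifetime, daily turnover) and its diagnostics;
* the crossover experimental designs (`condition_schedule()`,
  `replicate_runs()`, `no_switch_benefit()`, `switch_benefit()`);
* replicate statistics: relative SI benefit, per-capita efficiency by
  role, Poisson site persistency, carry-over profiles
  (`carryover_profile()`), and the preset experiment grids
  (`preset_experiments()`);
* command-line style runners (`cli_run()`, `cli_experiment()`, plus a thin
  launcher in `inst/scripts/waggleforage-cli.R`) that write CSV outputs
  and a JSON manifest sufficient to reproduce any result byte for byte.

## A worked example

Contrast a colony with spatial information against one without, in a
sparse landscape (1% of cells carry forage), over the published protocol
of 3 acclimatization days plus 48 experimental days:

```r
library(waggleforage)

p <- sim_params(d_patch = 0.01)
b <- no_switch_benefit(p, n_runs = 4, base_seed = 1)
round(c(SI = mean(b$si_run_means), NI = mean(b$ni_run_means),
        benefit_pct = b$benefit_pct))
#>          SI          NI benefit_pct
#>      200697       95545         110
```

SI colonies here net about 201 kJ of stored energy per day against 96 kJ
without spatial information — dances roughly double colony income when
food is hard to find. The same contrast measured *within* a 3-day
crossover design disappears entirely:

```r
s <- switch_benefit(p, cycle = "3", n_runs = 4, base_seed = 1)
round(s$benefit_pct, 1)
#> [1] -2.3
carryover_profile(s$runs$days)
#>   condition position mean_gain       se n_days
#> 1        NI        1  198715.2 15543.31     32
#> 3        NI        2  193087.0 15963.23     32
#> 5        NI        3  140723.7 15147.04     32
#> 2        SI        1  152133.7 13402.33     32
#> 4        SI        2  169205.8 15464.87     32
#> 6        SI        3  198928.0 15867.43     32
```

The carry-over profile shows why: the first day of each NI block still
earns SI-level income (198.7 kJ, decaying to 140.7 kJ by day three)
because recruits keep visiting the patches they were danced to during the
preceding SI block, while the first SI day is symmetrically depressed.
The within-design contrast measures almost nothing even though the true
benefit is about +110%.

A single full-scale run (51 days, 300 agents, 201×201 cells) takes about
a second:

```r
r <- run_simulation(sim_params(), seed = 1)
r
#> <sim_run> 51 days, 300 agents, seed 1
#>   mean experimental net gain: 308335 J/day; median trip distance: 1300 m
```

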