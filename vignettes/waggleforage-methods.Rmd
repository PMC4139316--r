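---
title: "Methods: the colony foraging model behind waggleforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the colony foraging model behind waggleforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Honeybee foragers that discover a profitable nectar source can advertise it
inside the nest with a waggle dance, which encodes the direction and
distance of the source.  Followers of an oriented dance acquire that vector
(spatial information, **SI**); if dances are disoriented, followers are
merely aroused and must search for themselves (**NI**).  Field experiments
that repeatedly switch a colony between SI and NI states have often failed
to detect benefits of the spatial vector.  `waggleforage` implements an
individual-based model built to examine one candidate explanation: recruits
are site-faithful, so a single successful recruitment event keeps paying
off for days; in a crossover design that income is booked partly under the
wrong treatment, biasing the measured contrast toward zero.

## Model overview

The world is a 201 x 201 grid of 100 m cells with the nest at the centre.
Each non-nest cell is a forage patch with probability `d_patch`; a patch
has a nectar quality drawn from a truncated normal (`q_mean` = 1.0,
`q_sd` = 0.2 mol/l, redrawn while below 0.05) and lives at most `a_max`
days.  Each morning patches age, over-age patches disappear, and empty
cells sprout new patches.  Two birth modes are provided:

* `"stationary"` (default): the per-day birth probability
  `d_patch / (a_max * (1 - d_patch))` balances the `1/a_max` per-day death
  rate, so long-run occupancy stays at `d_patch`, consistent with
  `d_patch`'s meaning as a patch *density*.
* `"literal"`: empty cells sprout with probability `d_patch` per day.  At
  defaults this drives occupancy to `d*a/(1 + d*a)` (about 0.41), an order
  of magnitude above the nominal density, which is why it is not the
  default; it is retained for comparison because the published description
  admits this reading.

Time advances in 10 s steps, 8640 per day, for 3 acclimatization days
(always SI) plus 48 experimental days.  Flight is possible between steps
138 and 4182 (06:23 to 17:37 with the day starting at 06:00); the
analytical day-length rule behind that window is not recoverable from the
source material, so the implied window is configured directly
(`forage_open`, `forage_close`) and does not change over the season.

A colony holds 30 scouts and 270 recruits.  Every agent pays `c_rest` =
0.04861 J per step in the nest and nine times that airborne or on a patch;
every step each agent dies with probability `m` = 7e-6 and is replaced by
a naive nestmate of the same role, keeping the population constant.  A
full load is 50 ul of nectar worth `quality * 282.25` J.

**Scouts** leave the nest with probability `p_exit` = 0.815 per step while
the window is open and search by a Levy flight: a uniformly random heading
and a leg length `(1 - a)^(1/(1 - mu_levy))` cell widths (minimum 1,
`mu_levy` = 2.4), re-drawn when the leg completes.  Search is saltatory:
the searcher scans for forage when a leg completes (at the reorientation
point), noticing a patch in the current cell with probability `p_detect`.
Feeding takes `Normal(180, 60)` steps (at flight metabolic rate), the
return flight is straight, and unloading takes `t_nest` = 6 steps.  During
each unloading step (while flying is still allowed) the forager dances
with probability `p_d x influx`, described below.  Scouts never carry a
site across days.

**Recruits** wait in the nest.  Under SI, each dance reaches `n_dance` = 1
waiting recruit, who learns the dancer's site with probability `p_dance` =
0.25 and will then commute straight to it, paying a one-off search penalty
`c_recruit` = 325 J on first arrival (recruits need several excursions to
localise an advertised site; the penalty summarises them).  Under NI a
dance simply sends one waiting recruit out scouting, with certainty and
without penalty.  Waiting recruits also self-start scouting with
probability `p_rs` = 9e-5 per step.  A recruit that holds a site revisits
it repeatedly within the day (exit probability `p_exit` per step) and
decides each morning whether to keep it; if the patch has died it finds
out on arrival, returns, and rejoins the waiting pool.

## The dance and abandonment curves

The published curves exist only as figure images, so the package treats
their *shape* as given and their placement as calibration.  Dancing is
logistic in the net energetic value of a trip,

    q_t = 282.25 q - (2 d / 70 m-per-step) * 0.4375 J - handling,
    p_d = plogis((q_t - dance_midpoint) / dance_slope),

which rises with quality and falls with distance (the quality sigmoid
right-shifts as distance grows, as in the source figures).  Dancing is
further suppressed by crowding: the dance probability is multiplied by a
factor falling linearly from 1 (no returns) to `influx_floor` = 0 at 20
returned foragers within the trailing `influx_window` = 60 steps (10 min),
flat beyond.  The next-day return probability is the dance curve shifted
up by `return_shift` = 0.30 and clamped at 1, the simplest form consistent
with its two published anchors (a source danced for 50% of the time is
revisited with probability 0.8; the offset is 30 percentage points
wherever unclamped).  Abandonment is the complement.  Setting
`persistent_recruits = FALSE` makes every experienced recruit forget its
site overnight, the control that removes carry-over.

## Calibration of the free constants

Two constants have no published value and materially shape the economy of
the model; both are first-class parameters, and their defaults were fixed
*once*, against the medium-density no-switch baseline (`d_patch` = 0.05,
`a_max` = 14), before the crossover experiments were examined:

* `p_detect` = 0.4.  Scan success at leg ends controls how hard
  independent search is.  The value was chosen so that scouts at the
  medium-density SI baseline net a small positive individual energy
  balance of order +200 J per scout-day (the study system reports scouts
  barely profitable, around +100 to +230 J/day across densities).  Larger
  values make self-search so easy that arousal (NI) rivals directed
  recruitment everywhere; smaller values starve the NI colonies at low
  density.
* `dance_midpoint` = net trip value of a 1.3 mol/l source at 2 km
  (about 235 J), `dance_slope` = a quarter of that.  This places the
  half-dance point clearly above the mean source quality, so foragers
  dance reliably only for distinctly above-average patches and the colony
  filters information.  With the midpoint at or below the mean quality,
  virtually every source is danced for and kept indefinitely, recruits
  saturate, and the SI/NI contrast inverts.

With these defaults the medium-density baseline shows median foraging
distances near 1.1 km (inside the realistic 0.5-2 km band), scout
per-capita nets near +200 J/day, a recruit-to-scout efficiency ratio just
above 1 (it exceeds 2 at low density), and mean site tenures near 2 days.

## Scheduling and numerical choices

* Each day: patch turnover, then morning keep/abandon decisions, then 8640
  steps.  Within a step, agents update in a freshly shuffled random order;
  mortality is applied after the behavioural updates.  This ordering is
  fixed for reproducibility; the source description leaves it open.
* When the foraging window is closed and every agent is idle in the nest,
  the remaining steps of the day are advanced in one batch (resting costs
  and mortality only) - a pure optimisation with the same distribution of
  outcomes.
* Each run owns a private xoshiro256++ random stream seeded from the run
  seed, so results are independent of R's RNG state and bitwise
  reproducible; replicate `i` of a set uses `base_seed + i - 1`.
* Truncations: feeding times are clamped to at least 1 step; quality
  redraws until above 0.05 mol/l; the return probability is clamped at 1.
* When the window closes, searching and feeding agents abort and fly home
  empty (costs still accrue); dancing requires the window to be open.
  Foragers already homing with a load still deliver it.
* Flying agents reflect at the world boundary; at default parameters
  foraging never reaches the 10 km edge, so the choice is inert.
* The energy ledger is exact by construction and asserted in tests: daily
  net gain = deliveries - step costs - recruitment penalties.
* Median trip distance is the median nest-to-patch Euclidean distance over
  the day's completed deliveries (NA on days without trips).
* A site tenure counts consecutive days on which a recruit actually fed at
  the same cell; spells end with abandonment, patch death discovered on
  arrival, agent death, or the end of the run.  Dance-recruited agents
  that never reach their site contribute no spell.

## What the generator emulates - and what it does not

The synthetic landscape reproduces the study conditions: stationary patch
density, truncated-normal quality, uniform initial ages, bounded patch
lifetime, no within-day depletion, no diurnal or seasonal structure, and
weather that always permits foraging.  Real foraging landscapes violate
most of these (patch quality co-varies with distance and time of day,
patches deplete, weather interrupts).  Passing tests therefore validate
the *mechanism* - long-term recruitment benefits and their contamination
of crossover designs - not quantitative predictions for any real habitat.

The absolute activity scale also deserves a caveat: under the published
handling times and exit probabilities, an established forager can complete
on the order of ten trips per day, so per-capita daily nets here are
several-fold larger than the few hundred J/day the original study prints.
Relative quantities (percentage benefits, ratios, orderings) are the
meaningful outputs; absolute J/day values should be read as
model-internal.

## Replication sizes

Experiments follow the published protocol of 12 runs per condition over 51
days; `replicate_runs()` splits switch designs evenly between SI-first and
NI-first schedules.  The test suite exercises the full-scale baseline
sparingly and otherwise uses miniature worlds (41 x 41 cells, 864-step
days, 6-9 day schedules) and 4-6 runs per condition for ordering checks;
`scripts/acceptance.R` recomputes every headline quantity at the full 12
runs x 51 days.  A single full-scale run takes on the order of a second.

## Known limitations

* The dance/abandonment calibration is anchored to reproduce baseline
  *behaviour*, not the unpublished curve values; headline percentages
  inherit that uncertainty, and strongly so where a ratio has a small
  denominator (the low-density and free-recruitment conditions).
* No receiver-bee queueing, crop capacity, brood demography, dance-floor
  spatial structure, or local search around an advertised site.
* `mu_levy` = 1 is outside the parameter space (the inverse-CDF exponent
  diverges), so the Levy sensitivity sweep covers 2-4.
* Initial colony energy is arbitrary (0); only daily differences are
  reported.
* An unsuccessful scout that returns empty re-enters the idle state and
  may exit again the same day; the source description does not say
  otherwise, and forbidding it would idle scouts for most of each day.
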