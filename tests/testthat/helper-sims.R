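# Small, fast configurations used across tests.

# A miniature day: 864 steps (~2.4 h of model time per "day") with a
# proportionally placed foraging window, on a 41 x 41 world.
tiny_params <- function(...) {
  sim_params(
    t_day = 864L, forage_open = 14L, forage_close = 418L,
    grid_half_extent = 20L, n_exp_days = 6L,
    ...
  )
}

# run a tiny no-switch simulation and return its day table
tiny_run <- function(params, condition = "SI", seed = 1L) {
  run_simulation(params, condition_schedule("none", condition, params), seed)
}
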