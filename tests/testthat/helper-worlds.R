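# Shared fixtures.  Heavy objects are built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# free-diffusion world (no interactions)
free_world <- function(seed = 1L)
  synthetic_world(wells = NULL, seed = seed)

# one deep bound basin, used for Boltzmann-consistency checks
one_well_world <- function(depth = 4, seed = 1L) {
  synthetic_world(wells = data.frame(d = 3, alpha1 = 0.6, alpha2 = 2.2,
                                     depth = depth, width_d = 0.4,
                                     width_alpha = 0.5),
                  seed = seed)
}

# the desk-scale study system for the end-to-end checks: the two mirror
# asymmetric basins, carved through the steric wall
two_basin_world <- function(seed = 7L) {
  synthetic_world(
    wells = data.frame(d = 3, alpha1 = c(0, pi), alpha2 = c(pi, 0),
                       depth = 11, width_d = 0.4, width_alpha = 0.5),
    wall_height = 6, seed = seed)
}

# moderate unbiased sampling of the two-basin world (shared across tests)
two_basin_sims <- function() fixture("two_basin_sims", function() {
  simulate_unbiased(two_basin_world(), n_traj = 20, n_steps = 30000,
                    dt = 5e-4, stride = 5L, seed = 7L)
})

# the full pipeline on the two-basin world; 30 us per trajectory keeps the
# sampling well past the ~2 us basin-exchange time (many binding events
# per trajectory) so that stationary weights are testable at the 3-SE level
two_basin_pipeline <- function() fixture("two_basin_pipeline", function() {
  run_dimer_pipeline(two_basin_world(),
                     n_traj = 20, n_steps = 60000, dt = 5e-4, stride = 5L,
                     lag = 20L, n_centers = 80L,
                     n_umbrella = 8L, umbrella_steps = 4000,
                     seed = 7L, contact_frames = 300L)
})

# small discrete truth shared by MSM/TRAM tests
truth20 <- function() fixture("truth20", function() {
  generate_discrete_truth(20, n_ensembles = 4, seed = 11L, n_blocks = 3,
                          coupling = 0.02, bias_scale = 1.5)
})
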