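# Shared desk-scale simulation results for the acceptance-style tests.
# These are the expensive Monte-Carlo experiments (minutes, not seconds);
# each is computed once per test run, on first use, and cached so several
# test blocks can interrogate the same data.

.sim_cache <- new.env(parent = emptyenv())

sim_get <- function(key, compute) {
  if (!exists(key, envir = .sim_cache)) assign(key, compute(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

SIM_SEED <- 20210302L

# outlier/modularity curves on the transition grids; the normal family's
# sharp sigmoid resolves at 15 replicates per tau, the lognormal family's
# shallower one needs 40 to pin the maximum-derivative grid point (the
# reference protocol uses 100)
sim_sweep <- function(family) {
  grid <- if (family == "normal") seq(3, 5.5, 0.25) else seq(4.5, 7, 0.25)
  reps <- if (family == "normal") 15 else 40
  sim_get(paste0("sweep_", family), function()
    tau_sweep(family, p_random = 0.2, tau_grid = grid, reps = reps,
              r = 4000, seed = SIM_SEED))
}

# two-stage experiment; normal networks probe robustness (tau_test = 4.15),
# specificity (3) and lock-in (5); the lognormal run at its own transition
# interval feeds the flexibility comparison
sim_two_stage <- function(family) {
  if (family == "normal")
    sim_get("two_stage_normal", function()
      two_stage("normal", tau_transition = 4.15, tau_test = c(4.15, 3, 5),
                reps = 60, seed = SIM_SEED))
  else
    sim_get("two_stage_lognormal", function()
      two_stage("lognormal", tau_transition = 5.5, tau_test = c(5.5, 4.5),
                reps = 60, seed = SIM_SEED))
}

sim_corr_lognormal <- function(tau) {
  sim_get(paste0("corr_lognormal_", tau), function()
    initial_final_correlation("lognormal", tau = tau, reps = 60, r = 4000,
                              seed = SIM_SEED))
}
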