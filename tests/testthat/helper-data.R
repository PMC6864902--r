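# Shared small fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# small planted dataset plus its extracted blocks (10^3 grid, 12 subjects)
shared_planted <- function() {
  if (!is.null(.fixture_env$planted)) return(.fixture_env$planted)
  truth <- make_ground_truth(grid_shape = c(10, 10, 10),
                             n_active_voxels = 120, seed = 7)
  ds <- simulate_dataset(truth, n_subjects = 12,
                         n_trials_per_condition = 6, seed = 21)
  dm <- extract_trial_windows(ds$bold, ds$events, ds$mask,
                              lag_count = 6, conditions = truth$conditions)
  seed_mean <- extract_seed_signal(dm, ds$seed_spec)
  dm_noseed <- exclude_voxels(dm, attr(seed_mean, "seed_voxels"))
  rt <- compute_condition_rt(ds$events, conditions = truth$conditions)
  vb <- assemble_variable_block(seed_mean, ds$fa, rt, tracts = "stria")
  .fixture_env$planted <- list(truth = truth, ds = ds, dm = dm,
                               dm_noseed = dm_noseed,
                               seed_mean = seed_mean, rt = rt, vb = vb)
  .fixture_env$planted
}

# noise-free, fully coupled dataset: downstream stacked matrix is rank 1
shared_noisefree <- function() {
  if (!is.null(.fixture_env$noisefree)) return(.fixture_env$noisefree)
  truth <- make_ground_truth(grid_shape = c(8, 8, 8), n_active_voxels = 60,
                             coupling_strength = 1, trial_snr = Inf,
                             seed = 3)
  ds <- simulate_dataset(truth, n_subjects = 8,
                         n_trials_per_condition = 3, seed = 5)
  dm <- extract_trial_windows(ds$bold, ds$events, ds$mask,
                              lag_count = 6, conditions = truth$conditions)
  seed_mean <- extract_seed_signal(dm, ds$seed_spec)
  dm_noseed <- exclude_voxels(dm, attr(seed_mean, "seed_voxels"))
  rt <- compute_condition_rt(ds$events, conditions = truth$conditions)
  vb <- assemble_variable_block(seed_mean, ds$fa, rt, tracts = "stria")
  st <- suppressWarnings(build_stacked_correlation_matrix(dm_noseed, vb))
  .fixture_env$noisefree <- list(truth = truth, ds = ds, dm = dm_noseed,
                                 vb = vb, stacked = st)
  .fixture_env$noisefree
}
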