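# Shared synthetic cohorts, built once per test run and memoized.

.cohort_cache <- new.env(parent = emptyenv())

# Full-size cohort matching the study's run length: used for parameter
# recovery, BOLD-variant agreement and planted-partition clustering.
recovery_cohort <- function() {
  if (is.null(.cohort_cache$rec)) {
    cfg <- sim_config(n_voxels = 300L, n_networks = 6L, n_timepoints = 490L,
                      n_subjects = 200L, noise_sd = 0.5, seed = 42L)
    cohort <- make_cohort(cfg)
    decomp <- rsn_decompose(cohort$runs, cohort$maps)
    .cohort_cache$rec <- list(cfg = cfg, cohort = cohort, decomp = decomp)
  }
  .cohort_cache$rec
}

# Small cohort for structural/netmats tests.
small_cohort <- function() {
  if (is.null(.cohort_cache$small)) {
    cfg <- sim_config(n_voxels = 120L, n_networks = 4L, n_timepoints = 240L,
                      n_subjects = 40L, seed = 7L)
    cohort <- make_cohort(cfg)
    decomp <- rsn_decompose(cohort$runs, cohort$maps)
    .cohort_cache$small <- list(cfg = cfg, cohort = cohort, decomp = decomp)
  }
  .cohort_cache$small
}
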