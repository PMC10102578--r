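# small synthetic worlds shared across test files

# cohort-scale config used by most statistical tests: defaults of the
# generator scaled down in size only (feature/subject counts), never in
# noise or effect magnitudes
small_cohort_config <- function(seed = 1L, ...) {
  args <- list(
    n_case = 28, n_control = 32, n_features = 500,
    n_differential = 81, n_up = 39,   # same fractions as the full design
    rng_seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# features that truly differ between groups: planted primaries plus the
# satellites that track a differential parent
true_differential <- function(truth) {
  d <- truth$differential$feature
  sat <- truth$satellite_map
  sort(c(d, sat$feature[sat$parent %in% d]))
}

# tiny raw-recording world for end-to-end preprocessing tests
tiny_raw_config <- function(seed = 7L, ...) {
  args <- list(
    n_case = 3, n_control = 3, n_features = 30, n_differential = 6,
    n_up = 3, isotope_fraction = 0.1, adduct_fraction = 0.05,
    rng_seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

simulate_raw_sample <- function(cohort, i, cfg, seed = 1000L + i, ...) {
  tr <- cohort$truth
  iso_parents <- tr$satellite_map$parent[tr$satellite_map$relation == "isotope_13C"]
  simulate_recording(cohort$abundances[i, ], tr$feature_mz, cfg,
                     carbon = tr$carbon, skip_isotope_for = iso_parents,
                     sample_id = cohort$cohort$sample_id[i], seed = seed, ...)
}
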