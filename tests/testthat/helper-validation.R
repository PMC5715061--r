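# Full-scale validation experiment shared by the acceptance tests: 30
# simulated subjects at the study defaults. Computed once per test run and
# cached; the heavy per-subject intermediates are kept for the FC-topology
# permutation checks.
validation_cache <- new.env(parent = emptyenv())

get_validation_report <- function() {
  if (is.null(validation_cache$report)) {
    validation_cache$report <- run_validation(sim_config(), n_subjects = 30,
                                              seed = 83, n_perm = 1000,
                                              keep_intermediates = TRUE)
  }
  validation_cache$report
}
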