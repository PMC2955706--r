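# Shared fixtures: noiseless parameter sets and small cohorts built in code.

noiseless_params <- function(...) {
  cycle_params(cv_mu = 0, cv_threshold = 0, cv_measurement = 0, v0_cv = 0,
               ...)
}

# A noiseless cohort of one cell under the given condition, sampled at
# 30-s intervals like the on-chip recordings.
noiseless_cohort <- function(condition, schedule_params, n = 1,
                             sampling_interval = 1 / 120) {
  spec <- cohort_spec(condition, n, schedule_params,
                      params = noiseless_params(),
                      sampling_interval = sampling_interval, seed = 1)
  generate_cohort(spec)
}
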