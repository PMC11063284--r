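# Shared fixtures: the benchmarked global parameter set and a few small
# cohorts built in code.

global_params <- cartrt_params()

# analytic untreated overall survival: ln(1e11 / 5e6) / rho
untreated_os <- function(p = global_params, n0 = 5e6, thr = 1e11) {
  log(thr / n0) / p$rho
}

# tiny noise-free, homogeneous two-group cohort for fitting tests
tiny_cohort <- function(n = 2, noise_cv = 0, variation = 0, seed = 11) {
  groups <- list(
    list(label = "Group-0", schedule = therapy_schedule(), n_mice = n),
    list(label = "T7", schedule = trt_schedule(7, 7.4), n_mice = n),
    list(label = "C7", schedule = cart_schedule(7, 1e6), n_mice = n))
  generate_cohort(
    cohort_spec(groups, noise_cv = noise_cv,
                mouse_variation = variation, seed = seed),
    global_params)
}
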