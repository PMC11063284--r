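test_that("exponential growth fit recovers an exact exponential", {
  d <- c(7, 14, 21)
  expect_equal(fit_exponential_growth(d, 5e6 * exp(0.27 * d)), 0.27,
               tolerance = 1e-10)
  # constant series: zero growth
  expect_equal(fit_exponential_growth(d, rep(2e6, 3)), 0, tolerance = 1e-12)
  expect_error(fit_exponential_growth(7, 5e6), "two observations")
  expect_error(fit_exponential_growth(d, c(1, -1, 1)), "positive")
})

test_that("mean fitted growth rate of a noisy control cohort is near truth", {
  p <- cartrt_params(rho = 0.27)
  coh <- generate_cohort(
    cohort_spec(list(list(label = "Group-0",
                          schedule = therapy_schedule(), n_mice = 8)),
                noise_cv = 0.2, mouse_variation = 0, seed = 5),
    p)
  obs <- coh$observations
  rhos <- vapply(unique(obs$mouse_id), function(id) {
    s <- obs[obs$mouse_id == id, ]
    fit_exponential_growth(s$day, s$value)
  }, 0)
  expect_lt(abs(mean(rhos) - 0.27) / 0.27, 0.10)
})

test_that("flux-to-cell conversion is a round-trip identity without noise", {
  coh <- generate_cohort(
    cohort_spec(list(list(label = "Group-0",
                          schedule = therapy_schedule(), n_mice = 4)),
                noise_cv = 0, mouse_variation = 0, bli_factor = 1234,
                seed = 3),
    global_params)
  conv <- estimate_bli_conversion(coh)
  expect_equal(conv$factor, 1234, tolerance = 1e-6)
  expect_equal(conv$rho, global_params$rho, tolerance = 1e-6)
  # doubling the assumed inoculum halves the factor
  conv2 <- estimate_bli_conversion(coh$observations, inoculum = 1e7)
  expect_equal(conv2$factor, conv$factor / 2, tolerance = 1e-9)
  expect_error(estimate_bli_conversion(coh$observations[0, ]), "empty")
})

test_that("individual refit reproduces data simulated from the global set", {
  coh <- tiny_cohort(n = 1)
  fit <- fit_individual(coh, global_params = global_params,
                        mouse_id = "T7-1", bli_factor = coh$bli_factor)
  expect_s3_class(fit, "cartrt_fit")
  expect_lt(fit$objective_value, 1e-8)
  expect_equal(coef(fit)[["rho"]], global_params$rho, tolerance = 1e-3)
  # bounds respected exactly
  est <- coef(fit)
  expect_true(all(est >= fit$bounds[, "lower"] - 1e-12))
  expect_true(all(est <= fit$bounds[, "upper"] + 1e-12))
  # objective trace over accepted iterations never increases
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("zero bound fraction returns the global parameters unchanged", {
  coh <- tiny_cohort(n = 1)
  fit <- fit_individual(coh, global_params = global_params,
                        mouse_id = "C7-1", bound_fraction = 0,
                        bli_factor = coh$bli_factor)
  expect_identical(coef(fit)[["rho"]], global_params$rho)
  expect_identical(coef(fit)[["k1"]], global_params$k1)
})

test_that("individual refit recovers a shifted rate inside the bounds", {
  # one control mouse whose true rho is 1.4x the global value: the +/-50%
  # box contains it, so the refit should land near 1.4x, not at the bound
  p_true <- cartrt_params(rho = 1.4 * global_params$rho)
  groups <- list(list(label = "Group-0", schedule = therapy_schedule(),
                      n_mice = 1))
  coh <- generate_cohort(cohort_spec(groups, noise_cv = 0,
                                     mouse_variation = 0, seed = 2),
                         p_true)
  fit <- fit_individual(coh, global_params = global_params,
                        mouse_id = "Group-0-1",
                        bli_factor = coh$bli_factor)
  expect_equal(coef(fit)[["rho"]], 1.4 * global_params$rho,
               tolerance = 0.02)
  expect_lt(coef(fit)[["rho"]], fit$bounds["rho", "upper"])
})

test_that("global joint fit recovers the truth from a noise-free suite", {
  coh <- generate_experiment_suite(global_params, n_per_group = 2,
                                   n_cart_only = 2, noise_cv = 0,
                                   mouse_variation = 0, seed = 8)
  fit <- fit_tumor_model(coh, multistart = 1, maxiter = 60)
  expect_s3_class(fit, "cartrt_fit")
  est <- coef(fit)
  for (nm in c("rho", "alpha_T", "k1", "theta", "k_cl"))
    expect_lt(abs(est[[nm]] - global_params[[nm]]) / global_params[[nm]],
              0.05)
  expect_lt(fit$objective_value, 1e-6)
  expect_length(fit$unidentifiable, 0)
})

test_that("fitting controls alone flags therapy parameters as uninformed", {
  coh <- tiny_cohort(n = 2)
  obs <- coh$observations[coh$observations$group == "Group-0", ]
  fit <- fit_tumor_model(obs,
                         schedules = list("Group-0" = therapy_schedule()),
                         bli_factor = coh$bli_factor, multistart = 1,
                         maxiter = 30)
  expect_true(all(c("alpha_T", "k1", "theta") %in% fit$unidentifiable))
  expect_true("alpha_T" %in% summary(fit)$table$parameter[
    summary(fit)$table$uninformed])
})

test_that("fit methods: predict, residuals, fitted and simulate cohere", {
  coh <- tiny_cohort(n = 1)
  fit <- fit_individual(coh, global_params = global_params,
                        mouse_id = "T7-1", bli_factor = coh$bli_factor)
  pr <- predict(fit)
  expect_length(pr, fit$n_obs)
  expect_equal(length(residuals(fit)), fit$n_obs)
  expect_lt(max(abs(residuals(fit))), 1e-4)
  expect_identical(fitted(fit), pr)
  sim <- simulate(fit, nsim = 1)
  expect_equal(sim[[1]][[1]]$cells, unname(pr), tolerance = 1e-8)
  # point prediction at a named day matches the trajectory
  one <- predict(fit, newdata = data.frame(mouse_id = "T7-1", day = 13))
  tr <- simulate_therapy(fit$params, coh$schedules[["T7"]], t_end = 20)
  expect_equal(one, tr$burden[which.min(abs(tr$times - 13))],
               tolerance = 1e-6)
})
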