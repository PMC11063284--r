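test_that("the six-group suite has the experimental design", {
  coh <- generate_experiment_suite(global_params, seed = 1)
  expect_equal(nrow(coh$truth), 47L)  # 5 groups of 8 plus 7
  counts <- table(coh$truth$group)
  expect_equal(unname(counts[["C7"]]), 7L)
  expect_true(all(counts[c("Group-0", "T7", "T7C18", "T7C25",
                           "T7C32")] == 8L))
  s25 <- coh$schedules[["T7C25"]]
  expect_equal(s25$day, c(7, 25))
  expect_equal(s25$kind, c("TRT", "CART"))
  expect_equal(s25$magnitude, c(7.4, 1e6))
  expect_equal(nrow(coh$schedules[["Group-0"]]), 0L)
})

test_that("noise-free homogeneous cohorts equal the deterministic model", {
  coh <- generate_experiment_suite(global_params, n_per_group = 1,
                                   n_cart_only = 1, noise_cv = 0,
                                   mouse_variation = 0, seed = 4)
  obs <- coh$observations
  for (g in c("Group-0", "T7C25")) {
    s <- obs[obs$group == g, ]
    tr <- simulate_therapy(global_params, coh$schedules[[g]],
                           t_end = max(s$day) + 1)
    model <- vapply(s$day, function(d)
      tr$burden[which.min(abs(tr$times - d))], 0)
    expect_equal(s$value, model * coh$bli_factor, tolerance = 1e-6)
  }
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_experiment_suite(global_params, seed = 42)
  b <- generate_experiment_suite(global_params, seed = 42)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  c <- generate_experiment_suite(global_params, seed = 43)
  expect_false(identical(a$observations$value, c$observations$value))
})

test_that("observations are positive and censoring is monotone", {
  coh <- generate_experiment_suite(global_params, seed = 2)
  obs <- coh$observations
  expect_true(all(obs$value > 0))
  # the endpoint censors the faster-growing control mice well before the
  # end of the observation grid
  ctrl <- obs[obs$group == "Group-0", ]
  n_days <- length(coh$spec$observation_days)
  expect_lt(nrow(ctrl), 8 * n_days)
  # once censored, a mouse never reappears: days are an unbroken prefix
  # of the observation grid
  grid <- coh$spec$observation_days
  for (id in unique(obs$mouse_id)) {
    d <- obs$day[obs$mouse_id == id]
    expect_identical(d, grid[seq_along(d)])
  }
})

test_that("measurement noise is lognormal with the stated spread", {
  coh <- generate_cohort(
    cohort_spec(list(list(label = "Group-0",
                          schedule = therapy_schedule(), n_mice = 60)),
                observation_days = c(6, 13, 20),
                noise_cv = 0.2, mouse_variation = 0, seed = 10),
    global_params)
  obs <- coh$observations
  truth <- vapply(obs$day, function(d)
    closed_form_burden(global_params, "untreated", d), 0)
  lr <- log(obs$value / (truth * coh$bli_factor))
  sigma <- sqrt(log(1 + 0.2^2))
  expect_equal(sd(lr), sigma, tolerance = 0.1)
  expect_equal(mean(exp(lr)), 1, tolerance = 0.03)
  expect_gt(shapiro.test(lr)$p.value, 0.01)
})

test_that("group-level PFS ordering puts the day-25 combination on top", {
  labs <- c("T7", "T7C18", "T7C25", "T7C32", "C7")
  coh <- generate_experiment_suite(global_params, n_per_group = 1,
                                   n_cart_only = 1, noise_cv = 0,
                                   mouse_variation = 0, seed = 1)
  pfs <- vapply(labs, function(g) {
    tr <- simulate_therapy(global_params, coh$schedules[[g]], t_end = 365)
    survival_metrics(tr)$pfs
  }, 0)
  expect_equal(names(which.max(pfs)), "T7C25")
})

test_that("cohorts round-trip through CSV plus sidecar", {
  coh <- generate_experiment_suite(global_params, n_per_group = 2,
                                   n_cart_only = 1, seed = 6)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$observations$value, coh$observations$value)
  expect_equal(back$observations$mouse_id, coh$observations$mouse_id)
  expect_equal(back$bli_factor, coh$bli_factor)
  expect_equal(back$truth$rho, coh$truth$rho)
  expect_equal(back$schedules[["T7C18"]]$day,
               coh$schedules[["T7C18"]]$day)
  unlink(f); unlink(sub("csv$", "json", f))
})
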