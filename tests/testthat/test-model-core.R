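test_that("radiation kill rate matches hand evaluation of the dose-rate law", {
  p <- global_params
  ev <- trt_schedule(7, 7.4)  # 0.2 uCi -> R0 = 0.288 Gy/day
  # at the administration instant: alpha_T * eta * 0.2
  expect_equal(radiation_kill_rate(p, 7, ev, "tumor"), 1.43 * 1.44 * 0.2,
               tolerance = 1e-12)
  # Heaviside: no contribution before the injection
  expect_identical(radiation_kill_rate(p, 6.999, ev, "tumor"), 0)
  # one mean-life later the rate has decayed by e
  expect_equal(radiation_kill_rate(p, 7 + 1 / p$lam, ev, "tumor"),
               1.43 * 1.44 * 0.2 * exp(-1), tolerance = 1e-12)
  # CAR-T radiosensitivity selects alpha_C
  expect_equal(radiation_kill_rate(p, 7, ev, "cart"), 1.01 * 1.44 * 0.2,
               tolerance = 1e-12)
  # two past administrations add
  ev2 <- therapy_schedule(c("TRT", "TRT"), c(7, 14), c(7.4, 7.4))
  expect_equal(radiation_kill_rate(p, 14, ev2, "tumor"),
               radiation_kill_rate(p, 14, ev, "tumor") + 1.43 * 1.44 * 0.2,
               tolerance = 1e-12)
})

test_that("state derivatives implement the model equations", {
  p <- global_params
  d <- model_derivatives(c(5e6, 0, 0), t = 3, p)
  expect_equal(unname(d), c(0.208 * 5e6, 0, 0))
  # CAR-T level balancing proliferation: dN_T/dt = 0
  nc_star <- p$rho / p$k1
  d2 <- model_derivatives(c(1e7, 0, nc_star), t = 3, p)
  expect_equal(unname(d2[1]), 0, tolerance = 1e-8)
  # with no CAR-T cells the k1 terms vanish identically
  ev <- trt_schedule(7, 7.4)
  d3 <- model_derivatives(c(1e7, 1e5, 0), t = 10, p, ev)
  kT <- radiation_kill_rate(p, 10, ev, "tumor")
  expect_equal(unname(d3), c(p$rho * 1e7 - kT * 1e7,
                             kT * 1e7 - p$k_cl * 1e5, 0))
  expect_error(model_derivatives(c(-1, 0, 0), 0, p), ">= 0")
})

test_that("simulated trajectories match the closed forms on their scenarios", {
  p0 <- cartrt_params(k2 = 0)
  # untreated exponential growth over 100 days
  tr <- simulate_therapy(global_params, therapy_schedule(), t_end = 100)
  cf <- closed_form_burden(global_params, "untreated", tr$times)
  expect_lt(max(abs(tr$burden - cf) / cf), 1e-6)
  expect_true(all(tr$N_R == 0) && all(tr$N_C == 0))
  # single-number check at day 7
  expect_equal(tr$burden[which.min(abs(tr$times - 7))],
               5e6 * exp(0.208 * 7), tolerance = 1e-7)
  # TRT-only: N_T has a closed form (exact whatever k2, as no CAR-T exist)
  tr2 <- simulate_therapy(p0, trt_schedule(7, 7.4), t_end = 100)
  cf2 <- closed_form_burden(p0, "trt_only_NT", tr2$times)
  expect_lt(max(abs(tr2$N_T - cf2) / cf2), 1e-6)
  # CAR-T only with k2 = 0
  tr3 <- simulate_therapy(p0, cart_schedule(7, 1e6), t_end = 100)
  cf3 <- closed_form_burden(p0, "cart_only_k2zero", tr3$times)
  expect_lt(max(abs(tr3$N_T - cf3) / cf3), 1e-6)
  # oracle sanity at t = 0 and unsupported scenario
  expect_equal(closed_form_burden(p0, "untreated", 0), 5e6)
  expect_error(closed_form_burden(p0, "sigmoidal", 10), "unsupported")
  expect_error(closed_form_burden(global_params, "cart_only_k2zero", 10),
               "k2")
})

test_that("trajectory before the first event equals untreated growth", {
  tr <- simulate_therapy(global_params, combo_schedule(7, 7.4, 25, 1e6),
                         t_end = 60)
  pre <- tr$times <= 7
  cf <- closed_form_burden(global_params, "untreated", tr$times[pre])
  expect_lt(max(abs(tr$burden[pre] - cf) / cf), 1e-8)
})

test_that("one TRT administration delivers total dose R0 / lambda", {
  p <- global_params
  R0 <- p$eta * kbq_to_uci(7.4)
  # integrate the implemented dose rate (kill rate / alpha) numerically
  dose <- stats::integrate(function(t)
    radiation_kill_rate(p, t, trt_schedule(7, 7.4), "tumor") / p$alpha_T,
    7, Inf, rel.tol = 1e-10)$value
  expect_equal(dose, R0 / p$lam, tolerance = 1e-6)
  expect_equal(R0 / p$lam, 1.44 * 0.2 / 0.07, tolerance = 1e-12)
})

test_that("simultaneous TRT doses superpose: two at A equal one at 2A", {
  two <- simulate_therapy(global_params,
                          therapy_schedule(c("TRT", "TRT"), c(7, 7),
                                           c(3.7, 3.7)), t_end = 80)
  one <- simulate_therapy(global_params, trt_schedule(7, 7.4), t_end = 80)
  expect_equal(two$N_T, one$N_T, tolerance = 1e-8)
  expect_equal(two$N_R, one$N_R, tolerance = 1e-8)
})

test_that("states stay nonnegative across a battery of random regimens", {
  set.seed(404)
  for (i in 1:12) {
    kinds <- sample(c("TRT", "CART"), 3, replace = TRUE)
    days <- sort(round(runif(3, 1, 60), 1))
    mags <- ifelse(kinds == "TRT", runif(3, 1, 15), 10^runif(3, 5, 6.5))
    tr <- simulate_therapy(global_params,
                           therapy_schedule(kinds, days, mags),
                           t_end = 120)
    expect_true(all(tr$N_T >= 0) && all(tr$N_R >= 0) && all(tr$N_C >= 0),
                info = paste("regimen", i))
    expect_true(all(diff(tr$times) > 0))
    expect_equal(tr$burden, tr$N_T + tr$N_R)
  }
})

test_that("CAR-T infusions are bolus jumps of the stated magnitude", {
  tr <- simulate_therapy(global_params, cart_schedule(10, 1e6),
                         t_end = 30)
  i <- which.min(abs(tr$times - 10))
  # output keeps the pre-bolus state at day 10; the next grid point (0.1
  # day later) shows the infused 1e6 cells less a small decay
  jump <- tr$N_C[i + 1] - tr$N_C[i]
  expect_gt(jump, 1e6 * exp(-global_params$theta * 0.1) * 0.999)
  expect_lt(jump, 1e6)
  expect_true(all(tr$N_C[tr$times < 10] == 0))
})
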