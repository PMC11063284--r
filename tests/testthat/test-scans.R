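test_that("timing scan agrees with standalone simulations", {
  sc <- scan_cart_timing(global_params, cart_days = c(10, 25, 40))
  for (d in c(10, 25, 40)) {
    tr <- simulate_therapy(global_params, combo_schedule(7, 7.4, d, 1e6),
                           t_end = 365)
    m <- survival_metrics(tr)
    row <- sc$table[sc$table$cart_day == d, ]
    expect_equal(row$pfs, m$pfs, tolerance = 1e-6)
    expect_equal(row$os, m$os, tolerance = 1e-6)
    expect_equal(row$t_min, m$t_min, tolerance = 1e-4)
  }
})

test_that("early CAR-T after TRT underperforms the optimum window", {
  sc <- scan_cart_timing(global_params, cart_days = c(8, 27))
  expect_lt(sc$table$pfs[sc$table$cart_day == 8],
            sc$table$pfs[sc$table$cart_day == 27])
})

test_that("an inert CAR-T dose makes the timing scan flat", {
  sc <- scan_cart_timing(global_params, cart_cells = 0,
                         cart_days = c(10, 20, 30, 40))
  expect_lt(diff(range(sc$table$pfs)), 1e-6)
  expect_equal(sc$argmax_set, c(10, 20, 30, 40))
})

test_that("argmax tie sets are nested as the tolerance grows", {
  sc1 <- scan_cart_timing(global_params, tie_eps = 0.1)
  sc2 <- scan_cart_timing(global_params, tie_eps = 0.5)
  sc3 <- scan_cart_timing(global_params, tie_eps = 1.0)
  expect_true(all(sc1$argmax_set %in% sc2$argmax_set))
  expect_true(all(sc2$argmax_set %in% sc3$argmax_set))
  expect_true(all(sc2$argmax_set >= 24 & sc2$argmax_set <= 34))
})

test_that("monotherapy dose scans behave monotonically", {
  sct <- scan_dose(global_params, "trt",
                   doses = seq(0.2, 2, by = 0.2) * 7.4)
  scc <- scan_dose(global_params, "cart",
                   doses = seq(0.2, 2, by = 0.2) * 1e6)
  # OS nondecreasing in dose for both therapies
  expect_true(all(diff(sct$table$os) >= -1e-6))
  expect_true(all(diff(scc$table$os) >= -1e-6))
  # a zero dose leaves the untreated outcome
  sc0 <- scan_dose(global_params, "cart", doses = c(0, 1e6))
  expect_identical(sc0$table$pfs[1], 0)
  expect_equal(sc0$table$os[1], untreated_os(), tolerance = 1e-3)
})

test_that("the CAR-T effective-dose threshold matches rho / k1", {
  sc <- scan_dose(global_params, "cart")
  analytic <- global_params$rho / global_params$k1  # ~6.91e5 cells
  grid <- sc$table$dose
  expect_equal(sc$min_effective_dose,
               min(grid[grid > analytic]))
})

test_that("a zero-interval split equals a single double administration", {
  tr_split <- simulate_therapy(global_params,
                               therapy_schedule(c("CART", "CART"),
                                                c(7, 7), c(0.5e6, 0.5e6)),
                               t_end = 100)
  tr_one <- simulate_therapy(global_params, cart_schedule(7, 1e6),
                             t_end = 100)
  expect_equal(tr_split$burden, tr_one$burden, tolerance = 1e-8)
  expect_equal(tr_split$N_C, tr_one$N_C, tolerance = 1e-8)
  # and the scan accepts second_day == first_day
  sc <- scan_split_dose(global_params, "cart", second_days = c(7, 9))
  m_one <- survival_metrics(tr_one)
  expect_equal(sc$table$pfs[sc$table$second_day == 7], m_one$pfs,
               tolerance = 1e-6)
})

test_that("parameter sampling is reproducible, bounded and centered", {
  s1 <- sample_parameter_sets(global_params, 0.5, n_sets = 1000, seed = 9)
  s2 <- sample_parameter_sets(global_params, 0.5, n_sets = 1000, seed = 9)
  expect_identical(s1$matrix, s2$matrix)
  for (nm in colnames(s1$matrix)) {
    lo <- s1$ranges[[nm]][1]; hi <- s1$ranges[[nm]][2]
    expect_true(all(s1$matrix[, nm] >= lo & s1$matrix[, nm] <= hi))
    # empirical mean near the interval midpoint at n = 1000
    expect_lt(abs(mean(s1$matrix[, nm]) - (lo + hi) / 2) / ((lo + hi) / 2),
              0.02)
  }
  # degenerate ranges reproduce the base set exactly
  s3 <- sample_parameter_sets(global_params, 0, n_sets = 1, seed = 1)
  expect_equal(unname(s3$matrix[1, "rho"]), global_params$rho)
  expect_error(sample_parameter_sets(global_params,
                                     ranges = list(rho = c(2, 1)),
                                     n_sets = 1),
               "range")
})

test_that("a degenerate sample reproduces the single-set argmax plateau", {
  s <- sample_parameter_sets(global_params, 0, n_sets = 1, seed = 1)
  h <- optimal_timing_histogram(s)
  sc <- scan_cart_timing(global_params)
  hit <- h$counts$day[h$counts$count > 0]
  expect_equal(hit, sc$argmax_set)
  # tie-inclusive counting: total mass at least one per set
  expect_gte(sum(h$counts$count), s$n_sets)
})

test_that("two-therapy map collapses to monotherapy when doses vanish", {
  sc <- scan_two_therapy_timing(global_params, trt_kbq = 0,
                                cart2_cells = 0,
                                trt_days = c(20, 30),
                                cart2_day_max = 40)
  mono <- survival_metrics(
    simulate_therapy(global_params, cart_schedule(7, 1e6), t_end = 365))
  expect_lt(diff(range(sc$table$pfs)), 1e-6)
  expect_equal(sc$table$pfs[1], mono$pfs, tolerance = 1e-6)
  expect_equal(sc$baseline_pfs, mono$pfs, tolerance = 1e-6)
})

test_that("two-therapy scan matches standalone three-administration runs", {
  sc <- scan_two_therapy_timing(global_params, trt_days = c(32, 34),
                                cart2_day_max = 60)
  for (k in c(1, nrow(sc$table))) {
    Td <- sc$table$trt_day[k]; Cd <- sc$table$cart2_day[k]
    tr <- simulate_therapy(global_params,
                           therapy_schedule(c("CART", "TRT", "CART"),
                                            c(7, Td, Cd),
                                            c(1e6, 7.4, 1e6)),
                           t_end = 365)
    m <- survival_metrics(tr)
    expect_equal(sc$table$pfs[k], m$pfs, tolerance = 1e-5)
  }
  # premature TRT right after the first infusion is suboptimal
  sc2 <- scan_two_therapy_timing(global_params, trt_days = c(8, 33),
                                 cart2_day_max = 70)
  pfs8 <- max(sc2$table$pfs[sc2$table$trt_day == 8])
  expect_lt(pfs8, sc2$max_pfs)
})
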