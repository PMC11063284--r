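# In-silico dosing and scheduling scans. All scans run the full simulator
# per grid point; the timing scans share the trajectory prefix common to
# all candidates (integration restarts at administration days make a
# scan-internal restart at a candidate day exactly equivalent to a
# standalone simulation of that regimen).

# One regimen -> metrics, on the fast array path with the solver stopped
# at the survival endpoint.
regimen_metrics <- function(params, trt_days = numeric(),
                            trt_kbq = numeric(), cart_days = numeric(),
                            cart_cells = numeric(), baseline_day = NULL,
                            initial_tumor = 5e6, t_end = 365,
                            death_threshold = 1e11, dt_out = 0.1) {
  m <- sim_core(params, trt_days, params$eta * kbq_to_uci(trt_kbq),
                cart_days, cart_cells, initial_tumor, t_end,
                dt_out = dt_out, stop_threshold = death_threshold)
  if (is.null(baseline_day)) {
    evd <- c(trt_days, cart_days)
    baseline_day <- if (length(evd)) min(evd) else NULL
  }
  metrics_core(m[, 1L], m[, 2L] + m[, 3L], baseline_day, death_threshold)
}

scan_result <- function(axis, table, argmax_set, max_pfs, tie_eps, params,
                        extra = list()) {
  structure(c(list(axis = axis, table = table, argmax_set = argmax_set,
                   max_pfs = max_pfs, tie_eps = tie_eps, params = params),
              extra),
            class = "cartrt_scan")
}

#' @export
print.cartrt_scan <- function(x, ...) {
  cat("Therapy scan over", x$axis, "(", nrow(x$table), "grid points )\n")
  cat(sprintf("  max PFS: %.2f days\n", x$max_pfs))
  if (is.data.frame(x$argmax_set)) {
    cat("  argmax set (ties within", x$tie_eps, "days of max):\n")
    print(x$argmax_set, row.names = FALSE)
  } else {
    cat("  argmax set (ties within", x$tie_eps, "days of max):",
        paste(x$argmax_set, collapse = ", "), "\n")
  }
  for (nm in intersect(c("min_effective_dose", "latest_effective_day",
                         "threshold_day"), names(x)))
    cat(" ", nm, ":", x[[nm]], "\n")
  invisible(x)
}

#' @export
plot.cartrt_scan <- function(x, ...) {
  if (x$axis == "trt_day x cart2_day") {
    td <- sort(unique(x$table$trt_day))
    cd <- sort(unique(x$table$cart2_day))
    z <- matrix(NA_real_, length(td), length(cd))
    z[cbind(match(x$table$trt_day, td), match(x$table$cart2_day, cd))] <-
      x$table$pfs
    graphics::image(td, cd, z, xlab = "TRT day", ylab = "second CAR-T day",
                    main = "PFS [days]", col = grDevices::hcl.colors(64),
                    ...)
  } else {
    xc <- x$table[[1L]]
    graphics::plot(xc, x$table$pfs, type = "b", pch = 16,
                   xlab = x$axis, ylab = "PFS [days]", ...)
  }
  invisible(x)
}

#' Scan the timing of a single CAR-T infusion after TRT
#'
#' With TRT fixed (default 7.4 kBq on day 7), varies the day of a single
#' CAR-T infusion across \code{cart_days} and computes PFS, OS and t_min
#' (measured from the TRT day) for each candidate. The maximal-PFS tie set
#' (all candidate days whose PFS lies within \code{tie_eps} of the
#' maximum) is reported as the optimal-timing set.
#'
#' @param params A \code{\link{cartrt_params}} object.
#' @param trt_day,trt_kbq TRT administration (day, activity in kBq).
#' @param cart_cells CAR-T cells infused.
#' @param cart_days Candidate infusion days (default 8 to 50).
#' @param tie_eps PFS tie tolerance in days for the argmax set.
#' @param initial_tumor,t_end,death_threshold Passed to the simulator.
#' @return A \code{"cartrt_scan"} object; \code{$table} holds one row per
#'   candidate day, \code{$argmax_set} the tied optimal days.
#' @examples
#' \donttest{
#' sc <- scan_cart_timing(cartrt_params())
#' sc$argmax_set
#' }
#' @export
scan_cart_timing <- function(params, trt_day = 7, trt_kbq = 7.4,
                             cart_cells = 1e6, cart_days = 8:50,
                             tie_eps = 0.5, initial_tumor = 5e6,
                             t_end = 365, death_threshold = 1e11) {
  stopifnot(all(cart_days > trt_day))
  cart_days <- sort(cart_days)
  R0 <- params$eta * kbq_to_uci(trt_kbq)
  # shared prefix: untreated to trt_day, then TRT-on to the last candidate
  pre <- run_segment(params, c(initial_tumor, 0, 0), 0, trt_day,
                     numeric(), numeric())
  y7 <- pre[nrow(pre), 2:4]
  stem <- run_segment(params, y7, trt_day, max(cart_days), trt_day, R0)
  res <- lapply(cart_days, function(d) {
    i <- which.min(abs(stem[, 1L] - d))
    y <- stem[i, 2:4]
    y[3L] <- y[3L] + cart_cells
    tail <- run_segment(params, y, stem[i, 1L], t_end, trt_day, R0,
                        stop_threshold = death_threshold)
    times <- c(pre[, 1L], stem[2:i, 1L], tail[-1L, 1L])
    burden <- c(pre[, 2L] + pre[, 3L],
                stem[2:i, 2L] + stem[2:i, 3L],
                tail[-1L, 2L] + tail[-1L, 3L])
    metrics_core(times, burden, trt_day, death_threshold)
  })
  tab <- data.frame(cart_day = cart_days,
                    pfs = vapply(res, `[[`, 0, "pfs"),
                    pfs_censored = vapply(res, `[[`, NA, "pfs_censored"),
                    os = vapply(res, `[[`, 0, "os"),
                    os_censored = vapply(res, `[[`, NA, "os_censored"),
                    t_min = vapply(res, `[[`, 0, "t_min"))
  mx <- max(tab$pfs)
  scan_result("cart_day", tab, cart_days[tab$pfs >= mx - tie_eps], mx,
              tie_eps, params)
}

#' Monotherapy dose scan
#'
#' Varies the dose of a TRT or CAR-T monotherapy delivered on
#' \code{admin_day} over a grid (default 20\% to 200\% of the experimental
#' dose, 7.4 kBq or 1e6 cells, in 5\% steps) and computes the survival
#' metrics per dose. Reports the minimum effective dose: the smallest grid
#' dose with nonzero PFS, i.e. the smallest dose that shrinks the tumor
#' below its size at treatment start rather than merely slowing it.
#'
#' @param params A \code{\link{cartrt_params}} object.
#' @param therapy \code{"trt"} or \code{"cart"}.
#' @param doses Dose grid (kBq for TRT, cells for CAR-T); default the
#'   20--200\% grid of the experimental dose.
#' @param admin_day Administration day.
#' @param tie_eps,initial_tumor,t_end,death_threshold As elsewhere.
#' @return A \code{"cartrt_scan"} with \code{$min_effective_dose}.
#' @examples
#' \donttest{
#' scan_dose(cartrt_params(), "cart")$min_effective_dose  # ~0.7e6 cells
#' }
#' @export
scan_dose <- function(params, therapy = c("trt", "cart"), doses = NULL,
                      admin_day = 7, tie_eps = 0.5, initial_tumor = 5e6,
                      t_end = 365, death_threshold = 1e11) {
  therapy <- match.arg(therapy)
  ref <- if (therapy == "trt") 7.4 else 1e6
  if (is.null(doses)) doses <- seq(0.2, 2, by = 0.05) * ref
  res <- lapply(doses, function(d) {
    if (therapy == "trt")
      regimen_metrics(params, trt_days = admin_day, trt_kbq = d,
                      initial_tumor = initial_tumor, t_end = t_end,
                      death_threshold = death_threshold)
    else
      regimen_metrics(params, cart_days = admin_day, cart_cells = d,
                      initial_tumor = initial_tumor, t_end = t_end,
                      death_threshold = death_threshold)
  })
  tab <- data.frame(dose = doses,
                    pfs = vapply(res, `[[`, 0, "pfs"),
                    pfs_censored = vapply(res, `[[`, NA, "pfs_censored"),
                    os = vapply(res, `[[`, 0, "os"),
                    os_censored = vapply(res, `[[`, NA, "os_censored"),
                    t_min = vapply(res, `[[`, 0, "t_min"))
  eff <- tab$dose[tab$pfs > 1e-9]
  mx <- max(tab$pfs)
  scan_result("dose", tab, tab$dose[tab$pfs >= mx - tie_eps], mx, tie_eps,
              params,
              extra = list(therapy = therapy,
                           min_effective_dose =
                             if (length(eff)) min(eff) else NA_real_))
}

#' Split-dose timing scan
#'
#' Splits the experimental dose into two equal administrations (default
#' 3.7 kBq each for TRT, 0.5e6 cells each for CAR-T), fixes the first on
#' \code{first_day} and varies the second over \code{second_days}.
#' Reports the latest second-administration day that still yields nonzero
#' PFS and the boundary day at which the advantage is lost (the first grid
#' day with zero PFS after the effective range).
#'
#' @param params A \code{\link{cartrt_params}} object.
#' @param therapy \code{"trt"} or \code{"cart"}.
#' @param per_admin_dose Dose per administration (kBq or cells).
#' @param first_day Day of the first administration.
#' @param second_days Candidate days for the second administration
#'   (>= \code{first_day}; equality reproduces a single double dose).
#' @param tie_eps,initial_tumor,t_end,death_threshold As elsewhere.
#' @return A \code{"cartrt_scan"} with \code{$latest_effective_day} and
#'   \code{$threshold_day}.
#' @examples
#' \donttest{
#' scan_split_dose(cartrt_params(), "cart")$threshold_day  # ~day 12
#' }
#' @export
scan_split_dose <- function(params, therapy = c("trt", "cart"),
                            per_admin_dose = NULL, first_day = 7,
                            second_days = 8:40, tie_eps = 0.5,
                            initial_tumor = 5e6, t_end = 365,
                            death_threshold = 1e11) {
  therapy <- match.arg(therapy)
  if (is.null(per_admin_dose))
    per_admin_dose <- if (therapy == "trt") 3.7 else 0.5e6
  stopifnot(all(second_days >= first_day))
  res <- lapply(second_days, function(d2) {
    days <- c(first_day, d2)
    if (therapy == "trt")
      regimen_metrics(params, trt_days = days,
                      trt_kbq = rep(per_admin_dose, 2L),
                      baseline_day = first_day,
                      initial_tumor = initial_tumor, t_end = t_end,
                      death_threshold = death_threshold)
    else
      regimen_metrics(params, cart_days = days,
                      cart_cells = rep(per_admin_dose, 2L),
                      baseline_day = first_day,
                      initial_tumor = initial_tumor, t_end = t_end,
                      death_threshold = death_threshold)
  })
  tab <- data.frame(second_day = second_days,
                    pfs = vapply(res, `[[`, 0, "pfs"),
                    pfs_censored = vapply(res, `[[`, NA, "pfs_censored"),
                    os = vapply(res, `[[`, 0, "os"),
                    os_censored = vapply(res, `[[`, NA, "os_censored"),
                    t_min = vapply(res, `[[`, 0, "t_min"))
  eff <- tab$second_day[tab$pfs > 1e-9]
  latest <- if (length(eff)) max(eff) else NA_real_
  thr <- if (length(eff)) {
    z <- tab$second_day[tab$pfs <= 1e-9 & tab$second_day > min(eff)]
    if (length(z)) min(z) else NA_real_
  } else NA_real_
  mx <- max(tab$pfs)
  scan_result("second_day", tab, tab$second_day[tab$pfs >= mx - tie_eps],
              mx, tie_eps, params,
              extra = list(therapy = therapy,
                           per_admin_dose = per_admin_dose,
                           latest_effective_day = latest,
                           threshold_day = thr))
}

#' Two-dimensional timing scan for the three-administration regimen
#'
#' First CAR-T infusion fixed (default 1e6 cells on day 7); the TRT day
#' and the day of a second CAR-T infusion are varied on a 2D grid
#' (\code{cart2_day > trt_day > cart1_day}). PFS is measured from the
#' first infusion. All grid pairs within \code{tie_eps} of the maximum
#' PFS form the argmax set.
#'
#' @param params A \code{\link{cartrt_params}} object.
#' @param cart1_day,cart1_cells First CAR-T infusion.
#' @param trt_kbq TRT activity, kBq.
#' @param cart2_cells Second CAR-T infusion dose.
#' @param trt_days Candidate TRT days (default 8 to 60).
#' @param cart2_day_max Latest candidate day for the second infusion
#'   (grid runs from \code{trt_day + 1} to this, 1-day steps).
#' @param tie_eps,initial_tumor,t_end,death_threshold As elsewhere.
#' @return A \code{"cartrt_scan"} whose \code{$table} has one row per
#'   (trt_day, cart2_day) pair and \code{$argmax_set} is a data frame of
#'   tied optimal pairs.
#' @examples
#' \donttest{
#' sc <- scan_two_therapy_timing(cartrt_params(), trt_days = seq(30, 38, 2),
#'                               cart2_day_max = 70)
#' head(sc$argmax_set)
#' }
#' @export
scan_two_therapy_timing <- function(params, cart1_day = 7,
                                    cart1_cells = 1e6, trt_kbq = 7.4,
                                    cart2_cells = 1e6, trt_days = 8:60,
                                    cart2_day_max = 100, tie_eps = 0.5,
                                    initial_tumor = 5e6, t_end = 365,
                                    death_threshold = 1e11) {
  stopifnot(all(trt_days > cart1_day), cart2_day_max > max(trt_days))
  trt_days <- sort(trt_days)
  R0 <- params$eta * kbq_to_uci(trt_kbq)
  pre <- run_segment(params, c(initial_tumor, 0, 0), 0, cart1_day,
                     numeric(), numeric())
  y1 <- pre[nrow(pre), 2:4]
  y1[3L] <- y1[3L] + cart1_cells
  # shared run from the first infusion across all candidate TRT days
  stemA <- run_segment(params, y1, cart1_day, max(trt_days), numeric(),
                       numeric())
  pre_t <- pre[, 1L]
  pre_b <- pre[, 2L] + pre[, 3L]
  rows <- list()
  for (Td in trt_days) {
    iT <- which.min(abs(stemA[, 1L] - Td))
    yT <- stemA[iT, 2:4]
    stemB <- run_segment(params, yT, stemA[iT, 1L], cart2_day_max, Td, R0)
    a_t <- stemA[2:iT, 1L]
    a_b <- stemA[2:iT, 2L] + stemA[2:iT, 3L]
    cart2_days <- seq(Td + 1L, cart2_day_max)
    for (Cd in cart2_days) {
      iC <- which.min(abs(stemB[, 1L] - Cd))
      yC <- stemB[iC, 2:4]
      yC[3L] <- yC[3L] + cart2_cells
      tail <- run_segment(params, yC, stemB[iC, 1L], t_end, Td, R0,
                          stop_threshold = death_threshold)
      times <- c(pre_t, a_t, stemB[2:iC, 1L], tail[-1L, 1L])
      burden <- c(pre_b, a_b,
                  stemB[2:iC, 2L] + stemB[2:iC, 3L],
                  tail[-1L, 2L] + tail[-1L, 3L])
      m <- metrics_core(times, burden, cart1_day, death_threshold)
      rows[[length(rows) + 1L]] <-
        c(Td, Cd, m$pfs, m$pfs_censored, m$os, m$os_censored, m$t_min)
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("trt_day", "cart2_day", "pfs", "pfs_censored", "os",
                  "os_censored", "t_min")
  tab$pfs_censored <- as.logical(tab$pfs_censored)
  tab$os_censored <- as.logical(tab$os_censored)
  mx <- max(tab$pfs)
  amax <- tab[tab$pfs >= mx - tie_eps, c("trt_day", "cart2_day", "pfs")]
  rownames(amax) <- NULL
  scan_result("trt_day x cart2_day", tab, amax, mx, tie_eps, params,
              extra = list(cart1_day = cart1_day,
                           baseline_pfs =
                             regimen_metrics(params,
                                             cart_days = cart1_day,
                                             cart_cells = cart1_cells,
                                             initial_tumor = initial_tumor,
                                             t_end = t_end,
                                             death_threshold =
                                               death_threshold)$pfs))
}

#' Sample virtual-population parameter sets
#'
#' Draws \code{n_sets} parameter vectors with the per-mouse-variable
#' parameters (\code{rho}, \code{alpha_T}, \code{k1}, \code{theta},
#' \code{k_cl}) sampled independently and uniformly within
#' \code{base * (1 +/- fraction)} (or explicit \code{ranges}); the
#' remaining parameters stay at their values in \code{base}, mirroring
#' which parameters were allowed to vary per mouse in calibration.
#'
#' @param base A \code{\link{cartrt_params}} object (interval midpoints).
#' @param fraction Half-width of the uniform interval as a fraction of the
#'   base value (default 0.5).
#' @param n_sets Number of parameter sets.
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param ranges Optional named list of \code{c(lo, hi)} per sampled
#'   parameter, overriding \code{fraction}.
#' @return An object of class \code{"cartrt_parameter_sample"}: list with
#'   the draw \code{matrix} (n_sets x 5), \code{base}, \code{ranges},
#'   \code{seed}.
#' @examples
#' s <- sample_parameter_sets(cartrt_params(), fraction = 0.5,
#'                            n_sets = 10, seed = 1)
#' colMeans(s$matrix)
#' @export
sample_parameter_sets <- function(base, fraction = 0.5, n_sets = 1000L,
                                  seed = 1L, ranges = NULL) {
  stopifnot(inherits(base, "cartrt_params"), n_sets >= 1)
  free <- free_parameter_names()
  if (is.null(ranges)) {
    stopifnot(fraction >= 0, fraction < 1)
    ranges <- lapply(free, function(nm)
      base[[nm]] * c(1 - fraction, 1 + fraction))
    names(ranges) <- free
  }
  for (nm in free) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[1L] > r[2L] || r[1L] < 0)
      stop("invalid sampling range for '", nm, "'")
  }
  set.seed(seed)
  m <- vapply(free, function(nm)
    stats::runif(n_sets, ranges[[nm]][1L], ranges[[nm]][2L]),
    numeric(n_sets))
  m <- matrix(m, nrow = n_sets,
              dimnames = list(NULL, free))
  structure(list(matrix = m, base = base, ranges = ranges, seed = seed,
                 n_sets = n_sets),
            class = "cartrt_parameter_sample")
}

#' @export
print.cartrt_parameter_sample <- function(x, ...) {
  cat("Virtual-population parameter sample:", x$n_sets, "sets, seed",
      x$seed, "\n")
  for (nm in colnames(x$matrix))
    cat(sprintf("  %-8s uniform [%.4g, %.4g]\n", nm, x$ranges[[nm]][1L],
                x$ranges[[nm]][2L]))
  invisible(x)
}

params_from_sample <- function(sample, i) {
  modify_params(sample$base, as.list(sample$matrix[i, ]))
}

histogram_result <- function(counts, mode, n_sets, extra = list()) {
  structure(c(list(counts = counts, mode = mode, n_sets = n_sets), extra),
            class = "cartrt_histogram")
}

#' @export
print.cartrt_histogram <- function(x, ...) {
  cat("Optimal-timing histogram over", x$n_sets, "parameter sets\n")
  if (is.list(x$mode) || length(x$mode) > 1L) {
    cat("  modes:", paste(names(x$mode), unlist(x$mode), sep = " = ",
                          collapse = ", "), "\n")
  } else {
    cat("  modal day:", x$mode, "\n")
  }
  cat("  total tied-optimum mass:",
      if (is.data.frame(x$counts)) sum(x$counts$count) else
        sum(vapply(x$counts, function(d) sum(d$count), 0)), "\n")
  invisible(x)
}

#' @export
plot.cartrt_histogram <- function(x, ...) {
  cnt <- if (is.data.frame(x$counts)) list(day = x$counts) else x$counts
  op <- graphics::par(mfrow = c(1, length(cnt)))
  on.exit(graphics::par(op))
  for (nm in names(cnt))
    graphics::barplot(cnt[[nm]]$count, names.arg = cnt[[nm]]$day,
                      xlab = nm, ylab = "count", ...)
  invisible(x)
}

#' Histogram of optimal single CAR-T infusion days over a virtual population
#'
#' Runs the CAR-T timing scan (\code{\link{scan_cart_timing}}) for every
#' parameter set in \code{sample} and accumulates every member of each
#' set's maximal-PFS tie set into a histogram of candidate infusion days
#' (tie-inclusive counting: a set with a 5-day plateau contributes 5
#' counts). The modal day is the infusion day most likely to maximize PFS
#' across the population.
#'
#' @param sample A \code{\link{sample_parameter_sets}} result.
#' @param ... Passed on to \code{\link{scan_cart_timing}}.
#' @return A \code{"cartrt_histogram"}: \code{$counts} (day, count),
#'   \code{$mode}.
#' @examples
#' \donttest{
#' s <- sample_parameter_sets(cartrt_params(), 0.5, n_sets = 5, seed = 1)
#' optimal_timing_histogram(s)$mode
#' }
#' @export
optimal_timing_histogram <- function(sample, ...) {
  stopifnot(inherits(sample, "cartrt_parameter_sample"))
  args <- list(...)
  cart_days <- if ("cart_days" %in% names(args)) args$cart_days else 8:50
  counts <- stats::setNames(integer(length(cart_days)),
                            as.character(cart_days))
  for (i in seq_len(sample$n_sets)) {
    sc <- do.call(scan_cart_timing,
                  c(list(params = params_from_sample(sample, i)), args))
    hit <- as.character(sc$argmax_set)
    counts[hit] <- counts[hit] + 1L
  }
  tab <- data.frame(day = cart_days, count = as.integer(counts))
  histogram_result(tab, tab$day[which.max(tab$count)], sample$n_sets)
}

#' Histograms of optimal TRT and second CAR-T days over a virtual population
#'
#' Runs the two-dimensional three-administration scan
#' (\code{\link{scan_two_therapy_timing}}) for every parameter set in
#' \code{sample}; every tied maximal-PFS (TRT day, second CAR-T day) pair
#' contributes one count to each of the two marginal histograms. A single
#' set typically contributes several tied pairs (a plateau on the 2D map),
#' so the total mass exceeds the number of sets.
#'
#' @param sample A \code{\link{sample_parameter_sets}} result.
#' @param ... Passed on to \code{\link{scan_two_therapy_timing}}.
#' @return A \code{"cartrt_histogram"} with \code{$counts} = list of two
#'   data frames (\code{trt_day}, \code{cart2_day}) and \code{$mode} =
#'   list of the two modal days.
#' @export
two_therapy_histogram <- function(sample, ...) {
  stopifnot(inherits(sample, "cartrt_parameter_sample"))
  args <- list(...)
  trt_days <- if ("trt_days" %in% names(args)) args$trt_days else 8:60
  c2max <- if ("cart2_day_max" %in% names(args)) args$cart2_day_max
           else 100
  cart2_days <- (min(trt_days) + 1L):c2max
  ct <- stats::setNames(integer(length(trt_days)), as.character(trt_days))
  cc <- stats::setNames(integer(length(cart2_days)),
                        as.character(cart2_days))
  for (i in seq_len(sample$n_sets)) {
    sc <- do.call(scan_two_therapy_timing,
                  c(list(params = params_from_sample(sample, i)), args))
    am <- sc$argmax_set
    for (k in seq_len(nrow(am))) {
      ct[as.character(am$trt_day[k])] <-
        ct[as.character(am$trt_day[k])] + 1L
      cc[as.character(am$cart2_day[k])] <-
        cc[as.character(am$cart2_day[k])] + 1L
    }
  }
  tabs <- list(trt_day = data.frame(day = as.integer(names(ct)),
                                    count = as.integer(ct)),
               cart2_day = data.frame(day = as.integer(names(cc)),
                                      count = as.integer(cc)))
  histogram_result(tabs,
                   list(trt_day =
                          tabs$trt_day$day[which.max(tabs$trt_day$count)],
                        cart2_day =
                          tabs$cart2_day$day[
                            which.max(tabs$cart2_day$count)]),
                   sample$n_sets)
}
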