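# Simulated survival endpoints. All three metrics are computed from the
# dense total-burden curve (N_T + N_R: irradiated-but-uncleared cells still
# carry viable-signal), within the window that ends at the survival
# endpoint -- the first time the burden reaches the death threshold (1e11
# cells). The continuous ODE regrows arbitrarily small populations, and at
# very large (post-endpoint) burdens the k2 expansion term produces
# recurrent CAR-T blooms; capping the window at the endpoint keeps the
# metrics on the physically meaningful part of the trajectory.

# Log-linear interpolated time at which `burden` first crosses `level`
# upward between grid points i and i+1.
cross_time <- function(times, burden, i, level) {
  b0 <- max(burden[i], .Machine$double.xmin)
  b1 <- max(burden[i + 1L], .Machine$double.xmin)
  if (b1 == b0) return(times[i + 1L])
  times[i] + (times[i + 1L] - times[i]) *
    (log(level) - log(b0)) / (log(b1) - log(b0))
}

# Shared implementation on bare arrays (fast path for the scans).
# Returns list(pfs, pfs_censored, os, os_censored, t_min, baseline_burden).
metrics_core <- function(times, burden, baseline_day,
                         death_threshold = 1e11) {
  n <- length(times)
  # overall survival: first upcrossing of the death threshold from day 0
  j <- which(burden >= death_threshold)
  if (length(j)) {
    j <- j[1L]
    os <- if (j == 1L) times[1L] else
      cross_time(times, burden, j - 1L, death_threshold)
    os_cens <- FALSE
    iend <- j
  } else {
    os <- times[n]
    os_cens <- TRUE
    iend <- n
  }
  if (is.null(baseline_day))
    return(list(pfs = NA_real_, pfs_censored = NA, os = os,
                os_censored = os_cens, t_min = NA_real_,
                baseline_burden = NA_real_, baseline_day = NA_real_))
  ib <- which(times >= baseline_day - 1e-9)[1L]
  if (is.na(ib)) stop("baseline day lies beyond the trajectory")
  B0 <- burden[ib]
  win <- ib:iend
  tw <- times[win]
  bw <- burden[win]
  below <- which(bw < B0 * (1 - 1e-9))
  if (!length(below)) {
    pfs <- 0
    pfs_cens <- FALSE
    t_min <- 0
  } else {
    lb <- below[length(below)]
    if (lb == length(bw)) {
      # still below baseline at the end of the window (horizon reached)
      pfs <- tw[lb] - baseline_day
      pfs_cens <- TRUE
    } else {
      pfs <- cross_time(tw, bw, lb, B0) - baseline_day
      pfs_cens <- FALSE
    }
    im <- which.min(bw)
    t_min <- tw[im] - baseline_day
    if (im > 1L && im < length(bw)) {
      # parabolic refinement of the argmin in log-burden
      lb3 <- log(pmax(bw[(im - 1L):(im + 1L)], .Machine$double.xmin))
      den <- lb3[1L] - 2 * lb3[2L] + lb3[3L]
      if (den > 0) {
        h1 <- tw[im] - tw[im - 1L]
        off <- 0.5 * (lb3[1L] - lb3[3L]) / den
        t_min <- t_min + max(min(off, 1), -1) * h1
      }
    }
    t_min <- max(t_min, 0)
  }
  list(pfs = pfs, pfs_censored = pfs_cens, os = os, os_censored = os_cens,
       t_min = t_min, baseline_burden = B0, baseline_day = baseline_day)
}

first_event_day <- function(traj) {
  if (nrow(traj$schedule) == 0L)
    stop("trajectory has no therapy events; survival metrics relative to ",
         "treatment start are undefined")
  min(traj$schedule$day)
}

#' Survival endpoints of a simulated therapy regimen
#'
#' Computes the three outcome metrics from a simulated trajectory:
#' \describe{
#'   \item{PFS}{progression-free survival: time from the start of treatment
#'     (the first administration) until the tumor burden, having dropped
#'     below its size at treatment start, has returned to that baseline
#'     size -- i.e. the last return-to-baseline crossing before the
#'     survival endpoint. Zero if the burden never drops below baseline.}
#'   \item{OS}{overall survival: time from tumor inoculation (day 0) until
#'     the total burden first reaches \code{death_threshold} (1e11 cells),
#'     located by log-linear interpolation on the dense output.}
#'   \item{t_min}{time from treatment start to the minimum tumor burden
#'     (zero when no reduction occurs).}
#' }
#' PFS and t_min are searched only up to the survival endpoint. If the
#' relevant crossing has not occurred by the end of the trajectory the
#' metric is censored at the horizon (flagged, never silently truncated).
#'
#' @param traj A \code{\link{simulate_therapy}} trajectory containing at
#'   least one therapy event (for OS alone, events are not required:
#'   see \code{\link{overall_survival}}).
#' @param baseline_day Day treatment starts; defaults to the first
#'   administration in the trajectory's schedule.
#' @param death_threshold Burden at the survival endpoint (cells).
#' @return An object of class \code{"cartrt_metrics"}: list with
#'   \code{pfs}, \code{pfs_censored}, \code{os}, \code{os_censored},
#'   \code{t_min}, \code{baseline_burden}, \code{baseline_day}.
#' @examples
#' p <- cartrt_params()
#' tr <- simulate_therapy(p, trt_schedule(7, 7.4), t_end = 200)
#' survival_metrics(tr)
#' @export
survival_metrics <- function(traj, baseline_day = NULL,
                             death_threshold = traj$death_threshold) {
  stopifnot(inherits(traj, "cartrt_trajectory"))
  if (is.null(baseline_day)) baseline_day <- first_event_day(traj)
  m <- metrics_core(traj$times, traj$burden, baseline_day, death_threshold)
  structure(m, class = "cartrt_metrics")
}

#' @export
print.cartrt_metrics <- function(x, ...) {
  cat("Simulated survival metrics\n")
  cat(sprintf("  baseline: day %g, burden %.4g cells\n",
              x$baseline_day, x$baseline_burden))
  cat(sprintf("  PFS  : %.2f days%s\n", x$pfs,
              if (isTRUE(x$pfs_censored)) " (censored at horizon)" else ""))
  cat(sprintf("  OS   : %.2f days%s\n", x$os,
              if (isTRUE(x$os_censored)) " (censored at horizon)" else ""))
  cat(sprintf("  t_min: %.2f days\n", x$t_min))
  invisible(x)
}

#' @rdname survival_metrics
#' @details \code{progression_free_survival}, \code{overall_survival} and
#'   \code{time_to_min_burden} return the single corresponding number;
#'   censoring is attached as attribute \code{"censored"}.
#' @export
progression_free_survival <- function(traj, baseline_day = NULL,
                                      death_threshold =
                                        traj$death_threshold) {
  m <- survival_metrics(traj, baseline_day, death_threshold)
  structure(m$pfs, censored = m$pfs_censored)
}

#' @rdname survival_metrics
#' @export
overall_survival <- function(traj, death_threshold =
                               traj$death_threshold) {
  stopifnot(inherits(traj, "cartrt_trajectory"))
  m <- metrics_core(traj$times, traj$burden, NULL, death_threshold)
  structure(m$os, censored = m$os_censored)
}

#' @rdname survival_metrics
#' @export
time_to_min_burden <- function(traj, baseline_day = NULL,
                               death_threshold = traj$death_threshold) {
  m <- survival_metrics(traj, baseline_day, death_threshold)
  m$t_min
}
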