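# Core integration of the three-compartment model. The system is solved
# piecewise between administration days (solver restart at every event), so
# the Heaviside therapy switches and CAR-T boluses never fall inside a
# solver step. The right-hand side is compiled C (src/cartrt_ode.c).

CARTRT_NMAX <- 16L

# Pack the 45-element parameter vector consumed by the C right-hand side.
pack_parms <- function(params, trt_days, trt_R0, n_active,
                       root_threshold = -1) {
  if (length(trt_days) > CARTRT_NMAX)
    stop("at most ", CARTRT_NMAX, " TRT administrations are supported")
  days <- rep(0, CARTRT_NMAX)
  r0 <- rep(0, CARTRT_NMAX)
  if (length(trt_days)) {
    days[seq_along(trt_days)] <- trt_days
    r0[seq_along(trt_R0)] <- trt_R0
  }
  g <- if (is.finite(params$gamma)) params$gamma else 0
  c(params$rho, params$k1, params$k2, params$theta, params$k_cl,
    params$alpha_T, params$alpha_C, params$lam,
    params$beta_T, params$beta_C, g,
    n_active, days, r0, root_threshold)
}

# Integrate one smooth segment [t0, t1] with a fixed set of active TRT
# administrations. Returns a matrix (time, y1..y3); attribute "rooted" is
# TRUE when the burden root stopped the solver inside the segment.
run_segment <- function(params, y, t0, t1, active_days, active_R0,
                        dt_out = 0.1, times_out = NULL,
                        stop_threshold = NULL, rtol = 1e-8, atol = 1e-3) {
  use_root <- !is.null(stop_threshold) && is.finite(stop_threshold)
  pv <- pack_parms(params, active_days, active_R0, length(active_days),
                   if (use_root) stop_threshold else -1)
  if (is.null(times_out)) {
    times <- seq(t0, t1, by = dt_out)
    if (times[length(times)] < t1 - 1e-12) times <- c(times, t1)
  } else {
    times <- sort(unique(c(t0, times_out[times_out > t0 + 1e-12 &
                                           times_out < t1 - 1e-12], t1)))
  }
  o <- if (use_root) {
    deSolve::lsodar(y, times, func = "cartrt_derivs", parms = pv,
                    dllname = "cartrt", initfunc = "cartrt_initmod",
                    rootfunc = "cartrt_root", nroot = 1L,
                    rtol = rtol, atol = atol)
  } else {
    deSolve::lsoda(y, times, func = "cartrt_derivs", parms = pv,
                   dllname = "cartrt", initfunc = "cartrt_initmod",
                   rtol = rtol, atol = atol)
  }
  m <- unclass(o)[, 1:4, drop = FALSE]
  neg <- min(m[, 2:4])
  if (neg < -atol)
    stop("integration produced a negative state (", signif(neg, 3),
         ") in segment [", t0, ", ", t1, "]")
  m[, 2:4][m[, 2:4] < 0] <- 0
  attr(m, "rooted") <- use_root && !is.null(attr(o, "troot")) &&
    length(attr(o, "troot")) > 0
  m
}

# Piecewise integration engine. Returns a matrix (time, N_T, N_R, N_C),
# truncated at the burden root if `stop_threshold` is set and reached.
sim_core <- function(params, trt_days, trt_R0, cart_days, cart_cells,
                     initial_tumor, t_end, dt_out = 0.1, times_out = NULL,
                     stop_threshold = NULL, rtol = 1e-8, atol = 1e-3) {
  y <- c(initial_tumor, 0, 0)
  # day-0 boluses apply to the initial state
  for (j in seq_along(cart_days))
    if (cart_days[j] <= 0) y[3] <- y[3] + cart_cells[j]
  ev <- sort(unique(c(trt_days, cart_days)))
  ev <- ev[ev > 0 & ev < t_end]
  bounds <- c(0, ev, t_end)
  out <- vector("list", length(bounds) - 1L)
  t0 <- 0
  for (k in seq_len(length(bounds) - 1L)) {
    t1 <- bounds[k + 1L]
    active <- which(trt_days <= t0 + 1e-9)
    m <- run_segment(params, y, t0, t1, trt_days[active], trt_R0[active],
                     dt_out = dt_out, times_out = times_out,
                     stop_threshold = stop_threshold,
                     rtol = rtol, atol = atol)
    out[[k]] <- if (k == 1L) m else m[-1L, , drop = FALSE]
    if (isTRUE(attr(m, "rooted"))) break
    y <- m[nrow(m), 2:4]
    t0 <- t1
    for (j in seq_along(cart_days))
      if (abs(cart_days[j] - t1) < 1e-9) y[3] <- y[3] + cart_cells[j]
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  dimnames(res) <- list(NULL, c("time", "N_T", "N_R", "N_C"))
  res
}

#' Simulate the tumor / CAR-T system through a therapy schedule
#'
#' Integrates the three-compartment model from inoculation (day 0) through
#' an arbitrary multi-administration schedule. CAR-T infusions are
#' instantaneous bolus additions to the CAR-T compartment; each TRT
#' injection switches on an exponentially decaying dose-rate kill term, and
#' the kill terms of multiple injections add. Integration restarts at every
#' administration day so no discontinuity falls inside a solver step.
#'
#' Cell counts are continuous and may fall below one cell and regrow: no
#' extinction cutoff is applied by default (set \code{eradication_threshold}
#' to clamp compartments that fall below a floor to zero).
#'
#' @param params A \code{\link{cartrt_params}} object.
#' @param schedule A \code{\link{therapy_schedule}} (may be empty).
#' @param initial_tumor Engrafted tumor cells at day 0 (default 5e6).
#' @param t_end Simulation horizon, days.
#' @param dt_out Output grid spacing, days (default 0.1, i.e. 10 points per
#'   day; the survival metrics root-find on this dense output).
#' @param stop_at_death If \code{TRUE}, stop integration when the total
#'   burden first reaches \code{death_threshold} (located by the solver's
#'   root finder). The survival metrics are unaffected: they never look
#'   beyond that crossing.
#' @param death_threshold Burden at the survival endpoint (default 1e11
#'   cells).
#' @param eradication_threshold Optional floor below which a compartment is
#'   treated as eradicated (clamped to zero at output points). Default
#'   \code{NULL}: off.
#' @param rtol,atol Relative and absolute integration tolerances
#'   (defaults 1e-8 and 1e-3 cells).
#'
#' @return An object of class \code{"cartrt_trajectory"}: list with
#'   \code{times}, \code{N_T}, \code{N_R}, \code{N_C}, \code{burden}
#'   (= N_T + N_R), plus the \code{schedule} and \code{params} used.
#' @examples
#' p <- cartrt_params()
#' tr <- simulate_therapy(p, combo_schedule(cart_day = 25), t_end = 120)
#' tr
#' @export
simulate_therapy <- function(params, schedule = therapy_schedule(),
                             initial_tumor = 5e6, t_end = 365,
                             dt_out = 0.1, stop_at_death = FALSE,
                             death_threshold = 1e11,
                             eradication_threshold = NULL,
                             rtol = 1e-8, atol = 1e-3) {
  stopifnot(inherits(params, "cartrt_params"),
            inherits(schedule, "cartrt_schedule"),
            initial_tumor > 0, t_end > 0)
  sc <- schedule_components(schedule, params$eta)
  m <- sim_core(params, sc$trt_days, sc$trt_R0, sc$cart_days,
                sc$cart_cells, initial_tumor, t_end, dt_out = dt_out,
                stop_threshold = if (stop_at_death) death_threshold,
                rtol = rtol, atol = atol)
  if (!is.null(eradication_threshold)) {
    m[, 2:4][m[, 2:4] < eradication_threshold] <- 0
  }
  structure(list(times = m[, "time"], N_T = m[, "N_T"], N_R = m[, "N_R"],
                 N_C = m[, "N_C"], burden = m[, "N_T"] + m[, "N_R"],
                 schedule = schedule, params = params,
                 initial_tumor = initial_tumor, t_end = t_end,
                 death_threshold = death_threshold),
            class = "cartrt_trajectory")
}

#' @export
print.cartrt_trajectory <- function(x, ...) {
  cat("TRT + CAR-T model trajectory\n")
  cat("  time span: 0 to", max(x$times), "days (",
      length(x$times), "points )\n")
  cat("  initial tumor:", format(x$initial_tumor, big.mark = ","),
      "cells\n")
  cat("  administrations:", nrow(x$schedule), "\n")
  cat("  final burden:", signif(x$burden[length(x$burden)], 4), "cells\n")
  invisible(x)
}

#' @export
as.data.frame.cartrt_trajectory <- function(x, ...) {
  data.frame(time_day = x$times, N_T = x$N_T, N_R = x$N_R, N_C = x$N_C,
             burden = x$burden)
}

#' @export
plot.cartrt_trajectory <- function(x, log = "y", ...) {
  b <- pmax(x$burden, 1)
  graphics::plot(x$times, b, type = "l", log = log,
                 xlab = "time [days since inoculation]",
                 ylab = "cells", col = "firebrick", lwd = 2, ...)
  if (any(x$N_C > 0))
    graphics::lines(x$times, pmax(x$N_C, 1), col = "steelblue", lwd = 2)
  ev <- x$schedule
  if (nrow(ev))
    graphics::abline(v = ev$day, lty = 3,
                     col = ifelse(ev$kind == "TRT", "darkorange",
                                  "steelblue"))
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("firebrick", "steelblue"),
                   legend = c("tumor burden (N_T + N_R)", "CAR-T (N_C)"))
  invisible(x)
}

#' Radiation-induced kill rate at a given time
#'
#' Evaluates the linear-quadratic dose-rate kill term summed over all TRT
#' administrations already delivered: each injection contributes
#' \eqn{\alpha_i R_0 e^{-\lambda (t - t_{TRT})}} plus, when the quadratic
#' radiosensitivity is nonzero, the sublethal-damage dose-rate correction.
#' \eqn{R_0 = \eta \times} activity (uCi). Administrations later than
#' \code{t} contribute zero (Heaviside switch).
#'
#' @param params A \code{\link{cartrt_params}} object.
#' @param t Time(s), days since inoculation (vectorized).
#' @param trt_events Data frame with columns \code{day} and
#'   \code{magnitude} (activity in kBq), or a
#'   \code{\link{therapy_schedule}} whose TRT rows are used.
#' @param cell_class \code{"tumor"} or \code{"cart"}: selects the
#'   radiosensitivity pair applied.
#' @return Kill rate(s), 1/day.
#' @examples
#' p <- cartrt_params()
#' radiation_kill_rate(p, t = 7, trt_schedule(7, 7.4), "tumor") # 0.41184
#' @export
radiation_kill_rate <- function(params, t, trt_events,
                                cell_class = c("tumor", "cart")) {
  cell_class <- match.arg(cell_class)
  stopifnot(inherits(params, "cartrt_params"))
  if (inherits(trt_events, "cartrt_schedule"))
    trt_events <- trt_events[trt_events$kind == "TRT", , drop = FALSE]
  alpha <- if (cell_class == "tumor") params$alpha_T else params$alpha_C
  beta <- if (cell_class == "tumor") params$beta_T else params$beta_C
  if (beta > 0 && !is.finite(params$gamma))
    stop("quadratic radiosensitivity requires a finite 'gamma'")
  out <- numeric(length(t))
  for (i in seq_len(nrow(trt_events))) {
    dt <- t - trt_events$day[i]
    R0 <- params$eta * kbq_to_uci(trt_events$magnitude[i])
    lin <- ifelse(dt >= 0, alpha * R0 * exp(-params$lam * dt), 0)
    quad <- 0
    if (beta > 0) {
      lam <- params$lam
      g <- params$gamma
      quad <- ifelse(dt >= 0,
                     2 * beta * R0^2 *
                       (exp(-2 * lam * dt) - exp(-(lam + g) * dt)) /
                       (g - lam),
                     0)
    }
    out <- out + lin + quad
  }
  out
}

#' Time derivatives of the model state
#'
#' Pure evaluation of the model right-hand side at one state and time:
#' tumor cells proliferate at rate \code{rho} and are lost to radiation
#' (moving into the irradiated compartment) and to CAR-T killing;
#' irradiated cells are cleared at \code{k_cl} and do not proliferate;
#' CAR-T cells expand in proportion to total tumor burden (\code{k2}),
#' die at rate \code{theta}, and are themselves radiosensitive.
#'
#' @param state Numeric vector \code{c(N_T, N_R, N_C)} (>= 0).
#' @param t Time, days since inoculation.
#' @param params A \code{\link{cartrt_params}} object.
#' @param schedule A \code{\link{therapy_schedule}}; only TRT rows with
#'   \code{day <= t} contribute radiation kill, and CAR-T rows matter only
#'   through the state (boluses are handled by the integrator).
#' @return Named numeric vector of derivatives \code{c(N_T, N_R, N_C)},
#'   cells/day.
#' @examples
#' model_derivatives(c(5e6, 0, 0), t = 3, cartrt_params(),
#'                   therapy_schedule())
#' @export
model_derivatives <- function(state, t, params,
                              schedule = therapy_schedule()) {
  stopifnot(length(state) == 3L, all(state >= 0))
  kT <- radiation_kill_rate(params, t, schedule, "tumor")
  kC <- radiation_kill_rate(params, t, schedule, "cart")
  NT <- state[1]; NR <- state[2]; NC <- state[3]
  c(N_T = params$rho * NT - kT * NT - params$k1 * NT * NC,
    N_R = kT * NT - params$k1 * NR * NC - params$k_cl * NR,
    N_C = params$k2 * (NT + NR) * NC - kC * NC - params$theta * NC)
}

#' Closed-form tumor burden for analytically solvable scenarios
#'
#' Analytic N_T(t) used as independent oracles for the integrator:
#' \describe{
#'   \item{untreated}{\eqn{N_0 e^{\rho t}}.}
#'   \item{trt_only_NT}{unirradiated compartment under a single TRT
#'     injection at \code{trt_day} (exact for N_T regardless of k2 since
#'     CAR-T are absent): for \eqn{\Delta = t - \tau \ge 0},
#'     \eqn{N(\tau) \exp[\rho\Delta - \alpha_T R_0 (1 - e^{-\lambda\Delta})/\lambda]}.}
#'   \item{cart_only_k2zero}{single CAR-T bolus at \code{cart_day} with
#'     \code{k2 = 0}, so the CAR-T pool decays exponentially:
#'     \eqn{N(\tau) \exp[\rho\Delta - k_1 N_{C0} (1 - e^{-\theta\Delta})/\theta]}.}
#' }
#'
#' @param params A \code{\link{cartrt_params}} object (with \code{k2 = 0}
#'   for the CAR-T scenario).
#' @param scenario One of \code{"untreated"}, \code{"trt_only_NT"},
#'   \code{"cart_only_k2zero"}.
#' @param t Time(s), days (vectorized).
#' @param initial_tumor Tumor cells at day 0.
#' @param trt_day,trt_kbq TRT scenario administration.
#' @param cart_day,cart_cells CAR-T scenario administration.
#' @return N_T(t), cells.
#' @examples
#' closed_form_burden(cartrt_params(), "untreated", t = 7)
#' @export
closed_form_burden <- function(params, scenario, t, initial_tumor = 5e6,
                               trt_day = 7, trt_kbq = 7.4,
                               cart_day = 7, cart_cells = 1e6) {
  stopifnot(inherits(params, "cartrt_params"))
  growth <- function(tt) initial_tumor * exp(params$rho * tt)
  switch(scenario,
    untreated = growth(t),
    trt_only_NT = {
      d <- pmax(t - trt_day, 0)
      R0 <- params$eta * kbq_to_uci(trt_kbq)
      growth(pmin(t, trt_day)) *
        exp(params$rho * d -
              params$alpha_T * R0 * (1 - exp(-params$lam * d)) /
                params$lam)
    },
    cart_only_k2zero = {
      if (params$k2 != 0)
        stop("the cart_only_k2zero oracle requires k2 = 0")
      d <- pmax(t - cart_day, 0)
      growth(pmin(t, cart_day)) *
        exp(params$rho * d -
              params$k1 * cart_cells * (1 - exp(-params$theta * d)) /
                params$theta)
    },
    stop("unsupported closed-form scenario: ", scenario)
  )
}
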