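# Calibration of model parameters to longitudinal tumor-burden cohorts:
# exponential growth rate from controls, bioluminescence-flux-to-cell
# conversion, a global joint fit across all treatment groups, and bounded
# per-mouse refits around the global optimum.

#' Exponential growth rate of a tumor burden series
#'
#' Ordinary least squares of log burden on day: the slope is the
#' exponential proliferation rate (1/day). Used on untreated control mice.
#'
#' @param day Observation days (>= 2 values).
#' @param value Positive burden values (flux or cells; the rate is
#'   scale-free).
#' @return The growth rate, 1/day.
#' @examples
#' fit_exponential_growth(c(7, 14, 21), 5e6 * exp(0.27 * c(7, 14, 21)))
#' @export
fit_exponential_growth <- function(day, value) {
  if (is.data.frame(day)) {
    value <- day$value
    day <- day$day
  }
  if (length(day) < 2L)
    stop("at least two observations are needed to fit a growth rate")
  if (any(value <= 0)) stop("burden values must be positive")
  unname(stats::coef(stats::lm(log(value) ~ day))[2L])
}

#' Bioluminescence-flux to cell-count conversion factor
#'
#' Back-calculates the day-0 flux of untreated control mice from their
#' mean flux at the earliest common observation day and their mean fitted
#' exponential growth rate, then divides by the known number of inoculated
#' cells: factor = mean_flux(d) * exp(-rho * d) / inoculum. Observed flux
#' divided by this factor estimates viable cell number.
#'
#' @param untreated Observations of the untreated group: data frame with
#'   columns \code{mouse_id}, \code{day}, \code{value} (flux).
#' @param inoculum Cells injected at day 0 (default 5e6).
#' @return List with \code{factor} (flux per cell), \code{rho} (mean
#'   fitted growth rate, 1/day) and \code{day_used}.
#' @export
estimate_bli_conversion <- function(untreated, inoculum = 5e6) {
  if (inherits(untreated, "cartrt_cohort"))
    untreated <- untreated_observations(untreated)
  if (nrow(untreated) == 0L) stop("empty untreated cohort")
  ids <- unique(untreated$mouse_id)
  rho <- mean(vapply(ids, function(id) {
    s <- untreated[untreated$mouse_id == id, ]
    fit_exponential_growth(s$day, s$value)
  }, 0))
  days_by_mouse <- lapply(ids, function(id)
    untreated$day[untreated$mouse_id == id])
  common <- Reduce(intersect, days_by_mouse)
  d0 <- if (length(common)) min(common) else min(untreated$day)
  fl <- mean(untreated$value[untreated$day == d0])
  list(factor = fl * exp(-rho * d0) / inoculum, rho = rho, day_used = d0)
}

untreated_observations <- function(cohort) {
  sch <- cohort$schedules
  untreated_groups <- names(sch)[vapply(sch, nrow, 0L) == 0L]
  cohort$observations[cohort$observations$group %in% untreated_groups, ]
}

# Per-mouse fitting records: schedule split into raw components (R0 is
# recomputed from the current eta inside the objective) plus observed cell
# counts.
prepare_mouse_data <- function(obs, schedules, bli_factor, floor) {
  lapply(split(obs, obs$mouse_id), function(s) {
    sched <- schedules[[s$group[1L]]]
    if (is.null(sched))
      stop("no schedule for group '", s$group[1L], "'")
    trt <- sched[sched$kind == "TRT", , drop = FALSE]
    cart <- sched[sched$kind == "CART", , drop = FALSE]
    cells <- s$value
    if (!is.null(s$value_unit) && any(s$value_unit == "flux"))
      cells <- ifelse(s$value_unit == "flux", s$value / bli_factor, cells)
    list(id = s$mouse_id[1L], group = s$group[1L], days = s$day,
         cells = pmax(cells, floor),
         trt_days = trt$day, trt_kbq = trt$magnitude,
         cart_days = cart$day, cart_cells = cart$magnitude)
  })
}

predict_mouse <- function(params, mouse, initial_tumor) {
  m <- sim_core(params, mouse$trt_days,
                params$eta * kbq_to_uci(mouse$trt_kbq),
                mouse$cart_days, mouse$cart_cells, initial_tumor,
                t_end = max(mouse$days) + 1e-6,
                times_out = mouse$days)
  b <- m[, 2L] + m[, 3L]
  idx <- vapply(mouse$days, function(d) which.min(abs(m[, 1L] - d)), 0L)
  b[idx]
}

make_objective <- function(mice, template, free, floor, initial_tumor) {
  function(logp) {
    params <- modify_params(template,
                            stats::setNames(as.list(10^logp), free))
    unlist(lapply(mice, function(mo) {
      # a corner of the search box may defeat the integrator (overflow at
      # extreme growth rates); such points get a large finite penalty so
      # the optimizer backs away instead of aborting the whole start
      pred <- tryCatch(
        pmax(predict_mouse(params, mo, initial_tumor), floor),
        error = function(e) rep(NA_real_, length(mo$days)))
      r <- log10(pred) - log10(mo$cells)
      r[!is.finite(r)] <- 20
      r
    }), use.names = FALSE)
  }
}

new_fit <- function(params, free, lower, upper, best, mice, floor,
                    initial_tumor, flagged) {
  structure(list(params = params, free_names = free,
                 bounds = cbind(lower = lower, upper = upper),
                 objective_value = best$deviance,
                 converged = best$info %in% 1:3,
                 trace = best$rsstrace,
                 n_obs = sum(vapply(mice, function(m) length(m$days), 0L)),
                 n_mice = length(mice), mice = mice, floor = floor,
                 initial_tumor = initial_tumor,
                 unidentifiable = flagged),
            class = "cartrt_fit")
}

run_bounded_fit <- function(mice, template, free, lower, upper, starts,
                            floor, initial_tumor, maxiter) {
  fn <- make_objective(mice, template, free, floor, initial_tumor)
  llo <- log10(lower)
  lup <- log10(upper)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(starts[s, ], llo), lup), fn = fn,
      lower = llo, upper = lup,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all optimizer starts failed for the bounded least-squares fit")
  best
}

# Structural identifiability screen: a parameter acting only through a
# therapy absent from every fitted schedule carries no signal.
structural_flags <- function(mice, free) {
  has_trt <- any(vapply(mice, function(m) length(m$trt_days) > 0, NA))
  has_cart <- any(vapply(mice, function(m) length(m$cart_days) > 0, NA))
  flagged <- character()
  if (!has_trt)
    flagged <- c(flagged, intersect(free, c("alpha_T", "alpha_C", "eta",
                                            "k_cl")))
  if (!has_cart)
    flagged <- c(flagged, intersect(free, c("k1", "k2", "theta",
                                            "alpha_C")))
  flagged
}

#' Fit the therapy model jointly to a multi-group mouse cohort
#'
#' The global calibration: one shared parameter vector is fitted to the
#' tumor burden series of all mice across all treatment groups
#' simultaneously, by bounded multi-start Levenberg-Marquardt least
#' squares on log10 burden. Flux observations are converted to cell
#' counts with a single scalar factor estimated from the untreated group
#' (\code{\link{estimate_bli_conversion}}) unless one is supplied.
#' Observations (and model predictions) below \code{floor} cells are
#' clipped to the floor before taking logs, a surrogate for the imaging
#' detection limit.
#'
#' @param cohort A \code{"cartrt_cohort"}
#'   (\code{\link{generate_experiment_suite}}) or a data frame with
#'   columns \code{mouse_id}, \code{group}, \code{day}, \code{value},
#'   \code{value_unit} (\code{"flux"} or \code{"cells"}).
#' @param schedules Named list mapping group labels to
#'   \code{\link{therapy_schedule}}s (taken from the cohort object when
#'   omitted).
#' @param init A \code{\link{cartrt_params}} giving starting values and
#'   the fixed values of non-free parameters.
#' @param free Names of the parameters optimized jointly; the default is
#'   the full set varied in the global calibration.
#' @param bounds_factor Multiplicative half-range of the search box:
#'   each free parameter is bounded to \code{init/bounds_factor} ..
#'   \code{init*bounds_factor}.
#' @param multistart Number of optimizer starts (the initial values plus
#'   Latin-hypercube draws over the log-bounded box).
#' @param seed Seed for the multi-start design.
#' @param floor Detection-limit surrogate, cells.
#' @param bli_factor Flux-per-cell factor; estimated from the untreated
#'   group when \code{NULL} and flux observations are present.
#' @param initial_tumor Inoculated cells at day 0.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class \code{"cartrt_fit"} with \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{residuals},
#'   \code{simulate} and \code{plot} methods. Fields include the fitted
#'   \code{params}, the \code{bounds}, the \code{objective_value} (sum of
#'   squared log10 residuals), the accepted-iteration objective
#'   \code{trace}, and \code{unidentifiable} (structurally uninformed
#'   parameters, e.g. radiosensitivity when no group received TRT).
#' @examples
#' \donttest{
#' coh <- generate_experiment_suite(cartrt_params(), n_per_group = 2,
#'                                  noise_cv = 0, mouse_variation = 0,
#'                                  seed = 1)
#' fit <- fit_tumor_model(coh, multistart = 1)
#' coef(fit)["rho"]
#' }
#' @export
fit_tumor_model <- function(cohort, schedules = NULL,
                            init = cartrt_params(),
                            free = c("rho", "eta", "alpha_T", "alpha_C",
                                     "k1", "k2", "theta", "k_cl"),
                            bounds_factor = 10, multistart = 8L,
                            seed = 1L, floor = 1e3, bli_factor = NULL,
                            initial_tumor = 5e6, maxiter = 100L) {
  if (inherits(cohort, "cartrt_cohort")) {
    if (is.null(schedules)) schedules <- cohort$schedules
    obs <- cohort$observations
  } else {
    obs <- cohort
  }
  if (is.null(schedules)) stop("group schedules are required")
  if (is.null(bli_factor) && any(obs$value_unit == "flux")) {
    grp_untreated <- names(schedules)[vapply(schedules, nrow, 0L) == 0L]
    if (!length(grp_untreated))
      stop("flux observations need an untreated group (or an explicit ",
           "'bli_factor') to estimate the flux-to-cell conversion")
    conv <- estimate_bli_conversion(
      obs[obs$group %in% grp_untreated, ], inoculum = initial_tumor)
    bli_factor <- conv$factor
  }
  mice <- prepare_mouse_data(obs, schedules, bli_factor, floor)
  stopifnot(bounds_factor > 1)
  lower <- vapply(free, function(nm) init[[nm]] / bounds_factor, 0)
  upper <- vapply(free, function(nm) init[[nm]] * bounds_factor, 0)
  set.seed(seed)
  starts <- rbind(log10(vapply(free, function(nm) init[[nm]], 0)))
  if (multistart > 1L) {
    u <- lhs::randomLHS(multistart - 1L, length(free))
    starts <- rbind(starts,
                    sweep(sweep(u, 2L, log10(upper) - log10(lower), "*"),
                          2L, log10(lower), "+"))
  }
  best <- run_bounded_fit(mice, init, free, lower, upper, starts, floor,
                          initial_tumor, maxiter)
  params <- modify_params(init,
                          stats::setNames(as.list(10^best$par), free))
  fit <- new_fit(params, free, lower, upper, best, mice, floor,
                 initial_tumor, structural_flags(mice, free))
  fit$bli_factor <- bli_factor
  fit
}

#' Bounded per-mouse refit around a global parameter set
#'
#' Refits one mouse's burden series with the per-mouse-variable parameters
#' (\code{rho}, \code{alpha_T}, \code{k1}, \code{theta}, \code{k_cl})
#' free within \code{global * (1 +/- bound_fraction)}; \code{eta},
#' \code{alpha_C}, \code{k2} and \code{lam} stay at their global values.
#' With \code{bound_fraction = 0} the global parameters are returned
#' unchanged.
#'
#' @param observations One mouse's series: data frame with \code{day},
#'   \code{value}, optional \code{value_unit}; or a \code{"cartrt_cohort"}
#'   together with \code{mouse_id}.
#' @param schedule The mouse's \code{\link{therapy_schedule}} (taken from
#'   the cohort when a cohort is supplied).
#' @param global_params The global \code{\link{cartrt_params}} (or a
#'   \code{"cartrt_fit"} whose parameters are used).
#' @param bound_fraction Fractional half-width of the per-parameter box
#'   (default 0.5).
#' @param mouse_id Mouse identifier when \code{observations} is a cohort.
#' @param multistart,seed,floor,bli_factor,initial_tumor,maxiter As in
#'   \code{\link{fit_tumor_model}}.
#' @return A \code{"cartrt_fit"} for the single mouse.
#' @export
fit_individual <- function(observations, schedule = NULL,
                           global_params, bound_fraction = 0.5,
                           mouse_id = NULL, multistart = 1L, seed = 1L,
                           floor = 1e3, bli_factor = NULL,
                           initial_tumor = 5e6, maxiter = 100L) {
  if (inherits(global_params, "cartrt_fit")) {
    if (is.null(bli_factor)) bli_factor <- global_params$bli_factor
    global_params <- global_params$params
  }
  if (inherits(observations, "cartrt_cohort")) {
    stopifnot(!is.null(mouse_id))
    obs <- observations$observations
    obs <- obs[obs$mouse_id == mouse_id, ]
    schedule <- observations$schedules[[obs$group[1L]]]
    observations <- obs
  }
  stopifnot(inherits(schedule, "cartrt_schedule"),
            bound_fraction >= 0, bound_fraction < 1)
  if (is.null(observations$group)) observations$group <- "mouse"
  if (is.null(observations$mouse_id)) observations$mouse_id <- "mouse"
  if (is.null(observations$value_unit)) observations$value_unit <- "cells"
  schedules <- stats::setNames(list(schedule), observations$group[1L])
  mice <- prepare_mouse_data(observations, schedules, bli_factor, floor)
  free <- free_parameter_names()
  if (bound_fraction == 0) {
    fn <- make_objective(mice, global_params, free, floor, initial_tumor)
    r <- fn(log10(vapply(free, function(nm) global_params[[nm]], 0)))
    best <- list(deviance = sum(r^2), info = 1L, rsstrace = sum(r^2),
                 par = log10(vapply(free, function(nm)
                   global_params[[nm]], 0)))
    return(new_fit(global_params, free,
                   vapply(free, function(nm) global_params[[nm]], 0),
                   vapply(free, function(nm) global_params[[nm]], 0),
                   best, mice, floor, initial_tumor,
                   structural_flags(mice, free)))
  }
  lower <- vapply(free, function(nm)
    global_params[[nm]] * (1 - bound_fraction), 0)
  upper <- vapply(free, function(nm)
    global_params[[nm]] * (1 + bound_fraction), 0)
  lower <- pmax(lower, 1e-300)
  set.seed(seed)
  starts <- rbind(log10(vapply(free, function(nm) global_params[[nm]], 0)))
  if (multistart > 1L) {
    u <- lhs::randomLHS(multistart - 1L, length(free))
    starts <- rbind(starts,
                    sweep(sweep(u, 2L, log10(upper) - log10(lower), "*"),
                          2L, log10(lower), "+"))
  }
  best <- run_bounded_fit(mice, global_params, free, lower, upper, starts,
                          floor, initial_tumor, maxiter)
  params <- modify_params(global_params,
                          stats::setNames(as.list(10^best$par), free))
  new_fit(params, free, lower, upper, best, mice, floor, initial_tumor,
          structural_flags(mice, free))
}

#' @export
print.cartrt_fit <- function(x, ...) {
  cat("Bounded least-squares fit of the TRT + CAR-T model\n")
  cat("  mice:", x$n_mice, "  observations:", x$n_obs, "\n")
  cat("  objective (sum sq log10 residuals):",
      signif(x$objective_value, 5),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  fitted parameters:\n")
  for (nm in x$free_names)
    cat(sprintf("    %-8s %.6g  [%.3g, %.3g]\n", nm, x$params[[nm]],
                x$bounds[nm, "lower"], x$bounds[nm, "upper"]))
  if (length(x$unidentifiable))
    cat("  structurally uninformed:",
        paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cartrt_fit <- function(object, ...) {
  stats::setNames(vapply(object$free_names,
                         function(nm) object$params[[nm]], 0),
                  object$free_names)
}

#' @export
summary.cartrt_fit <- function(object, ...) {
  est <- coef(object)
  tab <- data.frame(parameter = object$free_names, estimate = est,
                    lower = object$bounds[, "lower"],
                    upper = object$bounds[, "upper"],
                    at_bound = est <= object$bounds[, "lower"] *
                      (1 + 1e-6) |
                      est >= object$bounds[, "upper"] * (1 - 1e-6),
                    uninformed = object$free_names %in%
                      object$unidentifiable)
  rownames(tab) <- NULL
  out <- list(table = tab, objective_value = object$objective_value,
              rmse = sqrt(object$objective_value / object$n_obs),
              n_mice = object$n_mice, n_obs = object$n_obs,
              converged = object$converged)
  class(out) <- "summary.cartrt_fit"
  out
}

#' @export
print.summary.cartrt_fit <- function(x, ...) {
  cat("TRT + CAR-T model fit:", x$n_mice, "mice,", x$n_obs,
      "observations\n")
  cat("objective", signif(x$objective_value, 5), " rms log10 residual",
      signif(x$rmse, 3), "\n\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
predict.cartrt_fit <- function(object, newdata = NULL, ...) {
  mice <- object$mice
  if (is.null(newdata)) {
    unlist(lapply(mice, function(mo)
      predict_mouse(object$params, mo, object$initial_tumor)),
      use.names = FALSE)
  } else {
    stopifnot(all(c("mouse_id", "day") %in% names(newdata)))
    vapply(seq_len(nrow(newdata)), function(i) {
      mo <- mice[[as.character(newdata$mouse_id[i])]]
      if (is.null(mo)) stop("unknown mouse_id: ", newdata$mouse_id[i])
      mo$days <- newdata$day[i]
      predict_mouse(object$params, mo, object$initial_tumor)
    }, 0)
  }
}

#' @export
residuals.cartrt_fit <- function(object, ...) {
  obs <- unlist(lapply(object$mice, function(mo) log10(mo$cells)),
                use.names = FALSE)
  log10(pmax(predict(object), object$floor)) - obs
}

#' @export
fitted.cartrt_fit <- function(object, ...) predict(object)

#' @export
simulate.cartrt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    lapply(object$mice, function(mo) {
      m <- sim_core(object$params, mo$trt_days,
                    object$params$eta * kbq_to_uci(mo$trt_kbq),
                    mo$cart_days, mo$cart_cells, object$initial_tumor,
                    t_end = max(mo$days) + 1e-6, times_out = mo$days)
      idx <- vapply(mo$days, function(d)
        which.min(abs(m[, 1L] - d)), 0L)
      data.frame(mouse_id = mo$id, day = mo$days,
                 cells = m[idx, 2L] + m[idx, 3L])
    }))
}

#' @export
plot.cartrt_fit <- function(x, ...) {
  obs <- unlist(lapply(x$mice, function(mo) mo$cells), use.names = FALSE)
  prd <- pmax(predict(x), x$floor)
  graphics::plot(log10(obs), log10(prd),
                 xlab = "observed log10 cells",
                 ylab = "fitted log10 cells", pch = 16,
                 col = "#00000080", ...)
  graphics::abline(0, 1, col = "firebrick")
  invisible(x)
}
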