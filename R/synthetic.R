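# Synthetic mouse cohorts with the statistical structure of the six-group
# preclinical experiment: weekly bioluminescence-style observations of an
# engrafted disseminated myeloma burden under TRT and/or CAR-T therapy,
# multiplicative lognormal measurement noise, per-mouse parameter
# heterogeneity, and censoring at the survival endpoint.

#' Specification of a synthetic mouse cohort
#'
#' Collects everything needed to generate a cohort: group composition and
#' schedules, inoculum, observation days, noise level, per-mouse parameter
#' heterogeneity, flux conversion and seed.
#'
#' @param groups List of groups, each a list with \code{label},
#'   \code{schedule} (a \code{\link{therapy_schedule}}) and \code{n_mice}.
#' @param inoculum Tumor cells engrafted at day 0 (default 5e6).
#' @param observation_days Imaging days (default weekly from day 6,
#'   matching randomization 6 days after injection and weekly follow-up).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise (mean 1; default 0.2).
#' @param mouse_variation Uniform fractional half-width applied per mouse
#'   to \code{rho}, \code{alpha_T}, \code{k1}, \code{theta}, \code{k_cl}
#'   (default 0.5, the bound used for per-mouse refits).
#' @param bli_factor Photon flux per cell (arbitrary scale; only the
#'   round-trip through \code{\link{estimate_bli_conversion}} matters).
#' @param death_threshold Burden at which a mouse is censored (cells).
#' @param seed Integer seed: cohorts are reproducible bit-for-bit.
#' @return An object of class \code{"cartrt_cohort_spec"}.
#' @export
cohort_spec <- function(groups, inoculum = 5e6,
                        observation_days = seq(6, 83, by = 7),
                        noise_cv = 0.2, mouse_variation = 0.5,
                        bli_factor = 1e3, death_threshold = 1e11,
                        seed = 1L) {
  stopifnot(noise_cv >= 0, mouse_variation >= 0, mouse_variation < 1,
            inoculum > 0, bli_factor > 0)
  for (g in groups) {
    stopifnot(is.character(g$label),
              inherits(g$schedule, "cartrt_schedule"), g$n_mice >= 1)
  }
  structure(list(groups = groups, inoculum = inoculum,
                 observation_days = sort(observation_days),
                 noise_cv = noise_cv, mouse_variation = mouse_variation,
                 bli_factor = bli_factor,
                 death_threshold = death_threshold, seed = seed),
            class = "cartrt_cohort_spec")
}

#' Generate a synthetic mouse cohort
#'
#' For each mouse: draw its individual parameters uniformly within
#' \code{+/- mouse_variation} of \code{true_params} (the five per-mouse
#' parameters only), simulate its group's schedule from the inoculum,
#' read the total burden at the observation days, censor observations
#' after the burden reaches the death threshold, apply multiplicative
#' lognormal noise with mean 1 and CV \code{noise_cv}, and convert to
#' flux with \code{bli_factor}. The hidden per-mouse truth is retained
#' for parameter-recovery tests.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param true_params The population-center \code{\link{cartrt_params}}.
#' @return An object of class \code{"cartrt_cohort"}: list with
#'   \code{observations} (mouse_id, group, day, value, value_unit),
#'   \code{schedules} (named by group label), \code{truth} (per-mouse
#'   parameter draws), \code{bli_factor}, \code{spec}.
#' @examples
#' g <- list(list(label = "Group-0", schedule = therapy_schedule(),
#'                n_mice = 3))
#' coh <- generate_cohort(cohort_spec(g, seed = 7), cartrt_params())
#' head(coh$observations)
#' @export
generate_cohort <- function(spec, true_params = cartrt_params()) {
  stopifnot(inherits(spec, "cartrt_cohort_spec"),
            inherits(true_params, "cartrt_params"))
  set.seed(spec$seed)
  free <- free_parameter_names()
  sig <- sqrt(log(1 + spec$noise_cv^2))
  obs <- list()
  truth <- list()
  for (g in spec$groups) {
    sc <- schedule_components(g$schedule, true_params$eta)
    for (i in seq_len(g$n_mice)) {
      id <- sprintf("%s-%d", g$label, i)
      draw <- vapply(free, function(nm)
        stats::runif(1, true_params[[nm]] * (1 - spec$mouse_variation),
                     true_params[[nm]] * (1 + spec$mouse_variation)), 0)
      pm <- modify_params(true_params, as.list(draw))
      m <- sim_core(pm, sc$trt_days, pm$eta * kbq_to_uci(g$schedule$
                      magnitude[g$schedule$kind == "TRT"]),
                    sc$cart_days, sc$cart_cells, spec$inoculum,
                    t_end = max(spec$observation_days) + 1e-6,
                    times_out = spec$observation_days,
                    stop_threshold = spec$death_threshold)
      times <- m[, 1L]
      burden <- m[, 2L] + m[, 3L]
      keep_days <- spec$observation_days[spec$observation_days <=
                                           max(times) + 1e-9]
      idx <- vapply(keep_days, function(d)
        which.min(abs(times - d)), 0L)
      bd <- burden[idx]
      alive <- bd < spec$death_threshold
      keep_days <- keep_days[alive]
      bd <- bd[alive]
      noise <- exp(stats::rnorm(length(bd), -sig^2 / 2, sig))
      if (length(bd))
        obs[[id]] <- data.frame(
          mouse_id = id, group = g$label, day = keep_days,
          value = bd * noise * spec$bli_factor, value_unit = "flux",
          stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(mouse_id = id, group = g$label,
                                t(draw), stringsAsFactors = FALSE)
    }
  }
  schedules <- stats::setNames(lapply(spec$groups, `[[`, "schedule"),
                               vapply(spec$groups, `[[`, "", "label"))
  structure(list(observations = do.call(rbind, c(obs,
                                                 make.row.names = FALSE)),
                 schedules = schedules,
                 truth = do.call(rbind, c(truth,
                                          make.row.names = FALSE)),
                 bli_factor = spec$bli_factor, spec = spec),
            class = "cartrt_cohort")
}

#' Generate the six-group combination-therapy experiment
#'
#' Emulates the benchmark experiment: six groups -- untreated controls
#' (Group-0), TRT 7.4 kBq on day 7 (T7), TRT day 7 plus 1e6 CAR-T cells
#' on day 18 / 25 / 32 (T7C18, T7C25, T7C32), and CAR-T monotherapy 1e6
#' cells on day 7 (C7) -- with n = 8 mice per group except n = 7 for the
#' CAR-T-only group (47 mice in total), inoculation of 5e6 cells at day 0
#' and weekly observations from day 6.
#'
#' @param true_params Population-center \code{\link{cartrt_params}}.
#' @param n_per_group,n_cart_only Group sizes (defaults 8 and 7).
#' @param noise_cv,mouse_variation,bli_factor,observation_days,seed
#'   Passed to \code{\link{cohort_spec}}.
#' @return A \code{"cartrt_cohort"} (see \code{\link{generate_cohort}}).
#' @examples
#' coh <- generate_experiment_suite(cartrt_params(), n_per_group = 2,
#'                                  n_cart_only = 2, seed = 1)
#' table(coh$observations$group)
#' @export
generate_experiment_suite <- function(true_params = cartrt_params(),
                                      n_per_group = 8L, n_cart_only = 7L,
                                      noise_cv = 0.2,
                                      mouse_variation = 0.5,
                                      bli_factor = 1e3,
                                      observation_days = seq(6, 83,
                                                             by = 7),
                                      seed = 1L) {
  groups <- list(
    list(label = "Group-0", schedule = therapy_schedule(),
         n_mice = n_per_group),
    list(label = "T7", schedule = trt_schedule(7, 7.4),
         n_mice = n_per_group),
    list(label = "T7C18", schedule = combo_schedule(7, 7.4, 18, 1e6),
         n_mice = n_per_group),
    list(label = "T7C25", schedule = combo_schedule(7, 7.4, 25, 1e6),
         n_mice = n_per_group),
    list(label = "T7C32", schedule = combo_schedule(7, 7.4, 32, 1e6),
         n_mice = n_per_group),
    list(label = "C7", schedule = cart_schedule(7, 1e6),
         n_mice = n_cart_only))
  spec <- cohort_spec(groups, noise_cv = noise_cv,
                      mouse_variation = mouse_variation,
                      bli_factor = bli_factor,
                      observation_days = observation_days, seed = seed)
  generate_cohort(spec, true_params)
}

#' @export
print.cartrt_cohort <- function(x, ...) {
  cat("Synthetic mouse cohort\n")
  tab <- table(unique(x$truth[, c("mouse_id", "group")])$group)
  for (nm in names(x$schedules))
    cat(sprintf("  %-8s n=%d  %s\n", nm,
                if (nm %in% names(tab)) tab[[nm]] else 0L,
                if (nrow(x$schedules[[nm]]) == 0L) "untreated" else
                  paste(x$schedules[[nm]]$kind,
                        "d", x$schedules[[nm]]$day, collapse = " + ")))
  cat("  observations:", nrow(x$observations), " (flux, factor",
      x$bli_factor, "per cell)\n")
  invisible(x)
}

#' @export
as.data.frame.cartrt_cohort <- function(x, ...) x$observations
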