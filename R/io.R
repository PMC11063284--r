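# Plain-text interchange: parameters as flat JSON or YAML keyed by symbol
# name, schedules as JSON event lists with explicit units, trajectories
# and cohorts as CSV. Every reader round-trips its writer exactly.

#' Read and write model parameters
#'
#' Parameters are stored as a flat JSON or YAML mapping keyed by the
#' parameter names of \code{\link{cartrt_params}} (format chosen by file
#' extension: \code{.json}, \code{.yaml}/\code{.yml}).
#'
#' @param params A \code{\link{cartrt_params}} object.
#' @param path File path.
#' @return \code{read_params} returns a \code{cartrt_params};
#'   \code{write_params} returns \code{path} invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cartrt_params"))
  vals <- unclass(params)
  vals$gamma <- if (is.finite(vals$gamma)) vals$gamma else NULL
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cartrt_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown parameter(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(cartrt_params, vals)
}

#' Read and write therapy schedules
#'
#' A schedule is stored as a JSON array of events
#' \code{{kind, day, magnitude, unit}} with units \code{"kBq"} or
#' \code{"uCi"} for TRT and \code{"cells"} for CAR-T; uCi activities are
#' converted to kBq on read.
#'
#' @param schedule A \code{\link{therapy_schedule}}.
#' @param path File path.
#' @return \code{read_schedule} returns a \code{therapy_schedule};
#'   \code{write_schedule} returns \code{path} invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "cartrt_schedule"))
  events <- lapply(seq_len(nrow(schedule)), function(i)
    list(kind = schedule$kind[i], day = schedule$day[i],
         magnitude = schedule$magnitude[i],
         unit = if (schedule$kind[i] == "TRT") "kBq" else "cells"))
  jsonlite::write_json(events, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  events <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(events)) return(therapy_schedule())
  kind <- vapply(events, `[[`, "", "kind")
  day <- vapply(events, `[[`, 0, "day")
  mag <- vapply(events, `[[`, 0, "magnitude")
  unit <- vapply(events, function(e)
    if (is.null(e$unit)) NA_character_ else e$unit, "")
  bad <- !is.na(unit) &
    !(toupper(kind) == "TRT" & unit %in% c("kBq", "uCi") |
        toupper(kind) == "CART" & unit == "cells")
  if (any(bad))
    stop("inconsistent event unit(s) in ", path)
  mag[which(unit == "uCi")] <- uci_to_kbq(mag[which(unit == "uCi")])
  therapy_schedule(kind, day, mag)
}

#' Read and write simulated trajectories
#'
#' CSV with columns \code{time_day}, \code{N_T}, \code{N_R}, \code{N_C},
#' \code{burden}.
#'
#' @param traj A \code{\link{simulate_therapy}} trajectory.
#' @param path File path.
#' @return \code{read_trajectory} returns the trajectory table as a data
#'   frame; \code{write_trajectory} returns \code{path} invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path)
}

#' Read and write survival metrics
#'
#' Metrics are serialized as a flat JSON record \code{{pfs, pfs_censored,
#' os, os_censored, t_min, baseline_burden, baseline_day}}.
#'
#' @param metrics A \code{\link{survival_metrics}} object.
#' @param path File path.
#' @return \code{read_metrics} returns a \code{cartrt_metrics};
#'   \code{write_metrics} returns \code{path} invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "cartrt_metrics"))
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "cartrt_metrics")
}

#' Read and write mouse cohorts
#'
#' Observations go to a CSV with columns \code{mouse_id}, \code{group},
#' \code{day}, \code{value}, \code{value_unit}; the group-to-schedule map
#' and (for synthetic cohorts) the hidden per-mouse truth go to a JSON
#' sidecar written next to the CSV.
#'
#' @param cohort A \code{"cartrt_cohort"}.
#' @param path CSV path; the sidecar is \code{path} with extension
#'   \code{.json}.
#' @return \code{read_cohort} returns a \code{"cartrt_cohort"};
#'   \code{write_cohort} returns \code{path} invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cartrt_cohort"))
  utils::write.csv(cohort$observations, path, row.names = FALSE)
  side <- list(
    bli_factor = cohort$bli_factor,
    seed = cohort$spec$seed,
    schedules = lapply(cohort$schedules, function(s)
      lapply(seq_len(nrow(s)), function(i)
        list(kind = s$kind[i], day = s$day[i],
             magnitude = s$magnitude[i]))),
    truth = cohort$truth)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  schedules <- lapply(side$schedules, function(ev) {
    if (is.data.frame(ev) && nrow(ev))
      therapy_schedule(ev$kind, ev$day, ev$magnitude)
    else therapy_schedule()
  })
  structure(list(observations = obs, schedules = schedules,
                 truth = side$truth, bli_factor = side$bli_factor,
                 spec = list(seed = side$seed)),
            class = "cartrt_cohort")
}
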