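#' Therapy administration events and schedules
#'
#' A therapy schedule is an ordered table of administrations, each either a
#' TRT injection (activity in kBq) or a CAR-T cell infusion (cell count).
#' Same-day TRT + CAR-T administration is permitted.
#'
#' @param kind Character vector of \code{"TRT"} or \code{"CART"}.
#' @param day Administration day(s), days since tumor inoculation (>= 0).
#' @param magnitude Injected activity in kBq for TRT events, infused cell
#'   count for CART events (>= 0).
#'
#' @return An object of class \code{"cartrt_schedule"}: a data frame with
#'   columns \code{kind}, \code{day}, \code{magnitude}, sorted by day.
#' @examples
#' # TRT 7.4 kBq on day 7, 1e6 CAR-T cells on day 25
#' therapy_schedule(kind = c("TRT", "CART"), day = c(7, 25),
#'                  magnitude = c(7.4, 1e6))
#' @export
therapy_schedule <- function(kind = character(), day = numeric(),
                             magnitude = numeric()) {
  kind <- toupper(as.character(kind))
  day <- as.numeric(day)
  magnitude <- as.numeric(magnitude)
  if (length(kind) != length(day) || length(day) != length(magnitude))
    stop("'kind', 'day' and 'magnitude' must have equal length")
  if (!all(kind %in% c("TRT", "CART")))
    stop("event kind must be 'TRT' or 'CART'")
  if (any(!is.finite(day)) || any(day < 0))
    stop("event days must be finite and >= 0")
  if (any(!is.finite(magnitude)) || any(magnitude < 0))
    stop("event magnitudes must be finite and >= 0")
  o <- order(day, kind)
  structure(data.frame(kind = kind[o], day = day[o],
                       magnitude = magnitude[o],
                       stringsAsFactors = FALSE),
            class = c("cartrt_schedule", "data.frame"))
}

#' Common schedule shorthands
#'
#' Convenience constructors for the regimens used throughout: a single TRT
#' injection, a single CAR-T infusion, or the experimental TRT + CAR-T
#' combination.
#'
#' @param trt_day,trt_kbq TRT administration day and injected activity (kBq).
#' @param cart_day,cart_cells CAR-T infusion day and cell dose.
#' @return A \code{\link{therapy_schedule}}.
#' @examples
#' combo_schedule(trt_day = 7, cart_day = 25)
#' @export
trt_schedule <- function(trt_day = 7, trt_kbq = 7.4) {
  therapy_schedule("TRT", trt_day, trt_kbq)
}

#' @rdname trt_schedule
#' @export
cart_schedule <- function(cart_day = 7, cart_cells = 1e6) {
  therapy_schedule("CART", cart_day, cart_cells)
}

#' @rdname trt_schedule
#' @export
combo_schedule <- function(trt_day = 7, trt_kbq = 7.4, cart_day = 25,
                           cart_cells = 1e6) {
  therapy_schedule(c("TRT", "CART"), c(trt_day, cart_day),
                   c(trt_kbq, cart_cells))
}

#' @export
print.cartrt_schedule <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Therapy schedule: no administrations (untreated)\n")
    return(invisible(x))
  }
  cat("Therapy schedule (", nrow(x), " administration",
      if (nrow(x) > 1L) "s", "):\n", sep = "")
  for (i in seq_len(nrow(x))) {
    unit <- if (x$kind[i] == "TRT") "kBq" else "cells"
    cat(sprintf("  day %-6g %-5s %g %s\n", x$day[i], x$kind[i],
                x$magnitude[i], unit))
  }
  invisible(x)
}

# Split a schedule into the pieces the integrator needs: TRT events as
# (day, R0 in Gy/day) and CART events as (day, cells).
schedule_components <- function(schedule, eta) {
  stopifnot(inherits(schedule, "cartrt_schedule"))
  trt <- schedule[schedule$kind == "TRT", , drop = FALSE]
  cart <- schedule[schedule$kind == "CART", , drop = FALSE]
  list(trt_days = trt$day,
       trt_R0 = eta * kbq_to_uci(trt$magnitude),
       cart_days = cart$day,
       cart_cells = cart$magnitude)
}
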