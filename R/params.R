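#' Model parameters for the combined TRT + CAR-T therapy model
#'
#' Constructs and validates the full set of rate constants and
#' radiobiological constants of the tumor / irradiated-tumor / CAR-T
#' three-compartment model. Defaults are the benchmarked global parameter
#' set for the MM.1S multiple myeloma xenograft treated with
#' \eqn{^{225}}Ac-daratumumab TRT and CS1-targeted CAR-T cells.
#'
#' @param rho Tumor proliferation rate, 1/day.
#' @param k1 CAR-T cell killing rate, 1/day/cell.
#' @param k2 CAR-T cell proliferation/exhaustion rate, 1/day/cell.
#' @param theta CAR-T cell death rate, 1/day.
#' @param k_cl Clearance rate of irradiated tumor cells, 1/day.
#' @param alpha_T Tumor cell radiosensitivity, 1/Gy.
#' @param alpha_C CAR-T cell radiosensitivity, 1/Gy.
#' @param lam Effective dose-rate decay constant (physical decay plus
#'   biological clearance), 1/day.
#' @param eta Activity-to-dose-rate conversion factor, Gy/day/uCi.
#' @param beta_T,beta_C Quadratic (dose-squared) radiosensitivities, 1/Gy^2.
#'   Zero for high linear-energy-transfer alpha-particle therapy, the
#'   default here.
#' @param gamma Sublethal-damage repair rate, 1/day. Only meaningful when a
#'   quadratic radiosensitivity is nonzero; left unset (\code{NA}) by
#'   default, and any \code{beta_T}/\code{beta_C} > 0 without a finite
#'   \code{gamma} is an error.
#'
#' @return An object of class \code{"cartrt_params"}: a named list of the
#'   validated parameter values.
#' @examples
#' p <- cartrt_params()
#' p$rho
#' cartrt_params(rho = 0.27)
#' @export
cartrt_params <- function(rho = 0.208, k1 = 3.01e-7, k2 = 2.34e-14,
                          theta = 0.035, k_cl = 0.45, alpha_T = 1.43,
                          alpha_C = 1.01, lam = 0.07, eta = 1.44,
                          beta_T = 0, beta_C = 0, gamma = NA_real_) {
  p <- list(rho = rho, k1 = k1, k2 = k2, theta = theta, k_cl = k_cl,
            alpha_T = alpha_T, alpha_C = alpha_C, lam = lam, eta = eta,
            beta_T = beta_T, beta_C = beta_C, gamma = gamma)
  for (nm in setdiff(names(p), "gamma")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    if (v < 0)
      stop("parameter '", nm, "' must be nonnegative (got ", v, ")")
  }
  if ((p$beta_T > 0 || p$beta_C > 0)) {
    if (!is.finite(p$gamma))
      stop("a quadratic radiosensitivity (beta_T/beta_C) > 0 requires a ",
           "finite sublethal-damage repair rate 'gamma'")
    if (p$gamma < 0) stop("'gamma' must be nonnegative")
    if (p$gamma == p$lam)
      stop("'gamma' must differ from 'lam' for the dose-rate quadratic term")
  }
  structure(p, class = "cartrt_params")
}

#' @export
print.cartrt_params <- function(x, ...) {
  cat("TRT + CAR-T model parameters\n")
  lab <- c(rho = "tumor proliferation [1/day]",
           k1 = "CAR-T killing rate [1/day/cell]",
           k2 = "CAR-T proliferation/exhaustion [1/day/cell]",
           theta = "CAR-T death rate [1/day]",
           k_cl = "irradiated-cell clearance [1/day]",
           alpha_T = "tumor radiosensitivity [1/Gy]",
           alpha_C = "CAR-T radiosensitivity [1/Gy]",
           lam = "dose-rate decay constant [1/day]",
           eta = "activity to dose rate [Gy/day/uCi]",
           beta_T = "tumor quadratic radiosensitivity [1/Gy^2]",
           beta_C = "CAR-T quadratic radiosensitivity [1/Gy^2]",
           gamma = "sublethal damage repair [1/day]")
  for (nm in names(lab))
    cat(sprintf("  %-8s %-45s %g\n", nm, lab[[nm]], x[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.cartrt_params <- function(x, ...) {
  data.frame(parameter = names(unclass(x)),
             value = unlist(unclass(x), use.names = FALSE))
}

# Replace a subset of parameter values, re-validating.
modify_params <- function(params, values) {
  stopifnot(inherits(params, "cartrt_params"))
  p <- unclass(params)
  p[names(values)] <- values
  do.call(cartrt_params, p)
}

# Parameters refit per mouse / resampled per virtual subject; the rest stay
# at their global values (mirrors the bounded individual-mouse refits).
free_parameter_names <- function() c("rho", "alpha_T", "k1", "theta", "k_cl")

#' Convert injected activity between kBq and uCi
#'
#' 1 uCi = 37 kBq. The model works internally in uCi because the
#' activity-to-dose-rate factor \code{eta} is expressed in Gy/day/uCi,
#' while experimental activities are quoted in kBq.
#'
#' @param x Activity value(s).
#' @return Converted activity value(s).
#' @examples
#' kbq_to_uci(7.4)   # 0.2 uCi
#' @export
kbq_to_uci <- function(x) x / 37

#' @rdname kbq_to_uci
#' @export
uci_to_kbq <- function(x) x * 37
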