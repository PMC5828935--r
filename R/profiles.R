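#' Plasma concentration profiles
#'
#' A `concentration_profile` wraps an evaluator mapping time (h) to
#' plasma drug concentration (ng/mL) together with its interval of
#' validity. Profiles are produced by [pk_profile()] (simulated
#' pharmacokinetics) or [interpolate_observed_concentrations()] (spline
#' over observed concentrations) and consumed by the simulation and
#' estimation machinery; any object with this contract can be dropped in.
#'
#' @param fun vectorised function of time returning ng/mL.
#' @param support numeric length-2 interval of validity (h).
#' @param label optional description.
#' @return object of class `concentration_profile`.
#' @export
concentration_profile <- function(fun, support = c(0, Inf), label = "") {
  stopifnot(is.function(fun), length(support) == 2L, support[1] < support[2])
  structure(list(fun = fun, support = support, label = label),
            class = "concentration_profile")
}

#' Evaluate a concentration profile
#'
#' @param profile a [concentration_profile()].
#' @param t times (h); must lie within the profile's support.
#' @return concentrations, ng/mL.
#' @export
conc_at <- function(profile, t) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (any(t < profile$support[1] - 1e-9) || any(t > profile$support[2] + 1e-9)) {
    stop("time outside the concentration profile's support [",
         profile$support[1], ", ", profile$support[2], "] h", call. = FALSE)
  }
  profile$fun(t)
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile%s on [%g, %g] h\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else "",
              x$support[1], x$support[2]))
  invisible(x)
}

#' One-compartment first-order-absorption PK parameters
#'
#' Parameters of the simple oral pharmacokinetic model used to drive drug
#' concentration inputs: first-order absorption into a one-compartment
#' disposition model with apparent clearance and volume.
#'
#' @param ka first-order absorption rate constant, 1/h.
#' @param cl_f apparent oral clearance, L/h.
#' @param v_f apparent volume of distribution, L.
#' @return object of class `pk_params`.
#' @export
pk_params <- function(ka, cl_f, v_f) {
  vals <- c(ka = ka, cl_f = cl_f, v_f = v_f)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("pk_params must all be finite and positive")
  }
  structure(as.list(vals), class = "pk_params")
}

#' Simulated oral concentration profile with dose superposition
#'
#' Builds a [concentration_profile()] from a one-compartment
#' first-order-absorption model by linear superposition over the dosing
#' regimen. Each dose contributes the Bateman response
#' \deqn{C(t) = \frac{1000\,D}{V/F} \frac{k_a}{k_a - k_e}
#'   \left(e^{-k_e (t - t_D)} - e^{-k_a (t - t_D)}\right)}
#' for \eqn{t \ge t_D}, with \eqn{k_e = CL/F / (V/F)}; the factor 1000
#' converts mg/L to ng/mL. When \eqn{k_a = k_e} the analytic limit
#' \eqn{C(t) = (1000 D / (V/F))\, k t\, e^{-k t}} is used.
#'
#' @param params a [pk_params()].
#' @param doses data frame with columns `amount` (mg, > 0) and `time`
#'   (h), sorted by time.
#' @return a [concentration_profile()] valid at all times (the
#'   concentration is zero before the first dose).
#' @examples
#' pk <- pk_params(ka = 1, cl_f = 4.2, v_f = 30)
#' prof <- pk_profile(pk, data.frame(amount = 200, time = 0))
#' conc_at(prof, c(0, 2, 24))
#' @export
pk_profile <- function(params, doses) {
  stopifnot(inherits(params, "pk_params"), is.data.frame(doses),
            all(c("amount", "time") %in% names(doses)))
  if (nrow(doses) == 0L) stop("at least one dose is required")
  if (any(doses$amount <= 0)) stop("dose amounts must be positive")
  if (is.unsorted(doses$time)) stop("doses must be sorted by time")
  ka <- params$ka
  ke <- params$cl_f / params$v_f
  scale <- 1000 / params$v_f  # mg -> ng/mL per L
  amounts <- doses$amount
  dose_times <- doses$time
  fun <- function(t) {
    out <- numeric(length(t))
    for (i in seq_along(amounts)) {
      tau <- t - dose_times[i]
      on <- tau > 0
      if (!any(on)) next
      tt <- tau[on]
      contrib <- if (abs(ka - ke) < 1e-10) {
        amounts[i] * scale * ka * tt * exp(-ka * tt)
      } else {
        amounts[i] * scale * ka / (ka - ke) * (exp(-ke * tt) - exp(-ka * tt))
      }
      out[on] <- out[on] + contrib
    }
    pmax(out, 0)
  }
  concentration_profile(fun, support = c(-Inf, Inf),
                        label = "one-compartment oral PK")
}

#' Spline interpolation over observed drug concentrations
#'
#' Piecewise-polynomial (natural cubic spline) interpolation through
#' observed plasma concentrations, clipped at zero from below. The
#' profile is valid only between the first and last observation times.
#'
#' @param times observation times, h; strictly increasing, at least 3.
#' @param concs observed concentrations, ng/mL (\eqn{\ge 0}).
#' @return a [concentration_profile()] supported on
#'   `[min(times), max(times)]`.
#' @export
interpolate_observed_concentrations <- function(times, concs) {
  if (length(times) < 3L) stop("at least 3 concentration observations required")
  if (length(times) != length(concs)) stop("times and concs must have equal length")
  if (any(duplicated(times))) stop("duplicate observation times are not allowed")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(concs < 0)) stop("observed concentrations must be non-negative")
  sf <- stats::splinefun(times, concs, method = "natural")
  concentration_profile(function(t) pmax(sf(t), 0),
                        support = range(times),
                        label = "spline over observed concentrations")
}

#' A constant (steady-exposure) concentration profile
#'
#' Convenience wrapper for scenarios driven by a daily-average plasma
#' concentration rather than a full time course.
#'
#' @param conc constant concentration, ng/mL (\eqn{\ge 0}).
#' @return a [concentration_profile()] supported on all times.
#' @export
constant_profile <- function(conc) {
  if (!is.finite(conc) || conc < 0) stop("concentration must be non-negative")
  concentration_profile(function(t) rep(conc, length(t)),
                        support = c(-Inf, Inf), label = "constant exposure")
}
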