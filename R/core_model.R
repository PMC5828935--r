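#' Rates of change of serum and urine uric acid
#'
#' The turnover model of uric acid disposition. The amount of uric acid in
#' serum, \eqn{S_{UA}} (mg), balances a constant production rate against
#' parallel elimination by intestinal clearance and by renal excretion
#' (glomerular filtration scaled by the fractional excretion coefficient):
#' \deqn{dS_{UA}/dt = k_P - CL_I [S]_{UA} - GFR \, F_E \, [S]_{UA}}
#' \deqn{dU_{UA}/dt = GFR \, F_E \, [S]_{UA}}
#' with \eqn{[S]_{UA} = S_{UA}/V_{UA}}. Urine appearance is equated with
#' proximal-tubule excretion (no transport downstream of the proximal
#' tubule).
#'
#' @param s_ua amount of uric acid in the serum compartment, mg.
#' @param kp current production rate, mg/h (\eqn{\ge 0}).
#' @param fe current fractional excretion coefficient, in \[0, 1\].
#' @param phys a [physiology_state()].
#' @return named numeric vector `c(ds_ua = , du_ua = )` in mg/h.
#' @examples
#' phys <- physiology_state(60, 0.03, 12)
#' ua_derivatives(s_ua = 120 * 19, kp = phys$kp0, fe = phys$fe0, phys)
#' # steady state: ds_ua = 0, du_ua = 12.96
#' @export
ua_derivatives <- function(s_ua, kp, fe, phys) {
  validate_physiology_state(phys)
  for (nm in c("s_ua", "kp", "fe")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("ua_derivatives argument '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    }
  }
  if (kp < 0) stop("production rate kp must be non-negative")
  if (fe < 0 || fe > 1) stop("fractional excretion fe must lie in [0, 1]")
  conc <- s_ua / phys$v_ua
  du <- phys$gfr * fe * conc
  ds <- kp - phys$cl_i * conc - du
  c(ds_ua = ds, du_ua = du)
}

#' Steady-state serum concentration and urinary excretion rate
#'
#' Setting the serum balance to zero gives the steady-state serum
#' concentration and the corresponding urinary excretion rate:
#' \deqn{[S]_{UA} = \frac{k_P}{CL_I + GFR \, F_E}, \qquad
#'       X_{UA} = \frac{k_P \, GFR \, F_E}{CL_I + GFR \, F_E}}
#' The total clearance is \eqn{CL_{UA} = CL_I + GFR \, F_E}.
#'
#' @inheritParams ua_derivatives
#' @param kp production rate, mg/h; defaults to the baseline rate in `phys`.
#' @param fe fractional excretion coefficient; defaults to baseline.
#' @return object of class `ua_steady_state`: list with `conc` (mg/L),
#'   `x_ua` (mg/h) and `cl_total` (L/h).
#' @examples
#' phys <- physiology_state(60, 0.03, 12)
#' steady_state(phys)   # conc = 120 mg/L, x_ua = 12.96 mg/h
#' @export
steady_state <- function(phys, kp = phys$kp0, fe = phys$fe0) {
  validate_physiology_state(phys)
  if (kp < 0) stop("production rate kp must be non-negative")
  if (fe < 0 || fe > 1) stop("fractional excretion fe must lie in [0, 1]")
  cl_total <- phys$cl_i + phys$gfr * fe
  if (cl_total <= 0 && kp > 0) {
    stop("total clearance is zero with positive production: no finite steady state")
  }
  conc <- if (kp == 0) 0 else kp / cl_total
  structure(
    list(conc = conc, x_ua = conc * phys$gfr * fe, cl_total = cl_total),
    class = "ua_steady_state"
  )
}

#' @export
print.ua_steady_state <- function(x, ...) {
  cat(sprintf(
    "UA steady state: conc %.2f mg/L (%.2f mg/dL), excretion %.2f mg/h, CL %.3f L/h\n",
    x$conc, x$conc / 10, x$x_ua, x$cl_total))
  invisible(x)
}

#' Back-calculate the baseline production rate
#'
#' Inverts the steady state: given the drug-free serum concentration and
#' urinary excretion rate, the production rate is
#' \deqn{k_{P,0} = [S]_{UA} \times CL_I + X_{UA}}
#'
#' @param conc drug-free serum uric acid concentration, mg/L.
#' @param x_ua drug-free urinary excretion rate, mg/h.
#' @param cl_i intestinal clearance, L/h.
#' @return baseline production rate, mg/h.
#' @examples
#' baseline_production_rate(120, 12.96, 0.27)  # 45.36
#' @export
baseline_production_rate <- function(conc, x_ua, cl_i) {
  if (any(c(conc, x_ua, cl_i) < 0)) {
    stop("baseline_production_rate inputs must be non-negative")
  }
  conc * cl_i + x_ua
}

#' Back-calculate the baseline fractional excretion coefficient
#'
#' \deqn{F_{E,0} = \frac{X_{UA}}{[S]_{UA} \times GFR}}
#' Measured data can produce values above 1; that is flagged with a
#' warning (not an error) and left for downstream handling.
#'
#' @param conc drug-free serum uric acid concentration, mg/L (> 0).
#' @param x_ua drug-free urinary excretion rate, mg/h.
#' @param gfr glomerular filtration rate, L/h (> 0).
#' @return baseline fractional excretion coefficient.
#' @examples
#' baseline_fractional_excretion(120, 12.96, 3.6)  # 0.03
#' @export
baseline_fractional_excretion <- function(conc, x_ua, gfr) {
  if (x_ua < 0) stop("excretion rate x_ua must be non-negative")
  if (conc <= 0) stop("serum concentration must be positive to compute FE,0")
  if (gfr <= 0) stop("GFR must be positive to compute FE,0")
  fe0 <- x_ua / (conc * gfr)
  if (fe0 > 1) {
    warning("computed FE,0 exceeds 1 (", format(fe0),
            "); measured inputs are likely noisy", call. = FALSE)
  }
  fe0
}
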