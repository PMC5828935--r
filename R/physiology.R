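#' A subject's uric acid disposition parameters
#'
#' Bundles the physiological parameters that determine uric acid
#' disposition for one (possibly virtual) subject or treatment group:
#' glomerular filtration rate, baseline fractional excretion coefficient,
#' baseline production rate, volume of distribution, intestinal clearance
#' and the baseline serum uric acid concentration.
#'
#' Clinical units are accepted at this boundary (GFR in mL/min, serum
#' uric acid in mg/dL) and converted to the internal unit system
#' (mg, L, h). The baseline production rate `kp0` is, unless supplied
#' explicitly, back-calculated from the drug-free steady state:
#' \deqn{k_{P,0} = [S]_{UA} \times CL_I + X_{UA}, \qquad
#'       X_{UA} = GFR \times F_{E,0} \times [S]_{UA}}
#' so every `physiology_state` is internally consistent: its baseline
#' serum concentration is exactly the drug-free steady state.
#'
#' @param gfr_ml_min glomerular filtration rate, mL/min.
#' @param fe0 baseline fractional excretion coefficient, in (0, 1].
#' @param s_ua_base_mg_dl baseline serum uric acid, mg/dL.
#' @param v_ua volume of distribution of uric acid, L (default 19).
#' @param cl_i intestinal clearance of uric acid, L/h (default 0.27).
#' @param kp0 optional baseline production rate, mg/h. When omitted it is
#'   derived from the steady-state relation above.
#' @return an object of class `physiology_state` with fields `gfr` (L/h),
#'   `fe0`, `kp0` (mg/h), `v_ua` (L), `cl_i` (L/h) and `s_ua_base` (mg/L).
#' @examples
#' phys <- physiology_state(gfr_ml_min = 60, fe0 = 0.03,
#'                          s_ua_base_mg_dl = 12)
#' phys$kp0   # 45.36 mg/h
#' @export
physiology_state <- function(gfr_ml_min, fe0, s_ua_base_mg_dl,
                             v_ua = 19, cl_i = 0.27, kp0 = NULL) {
  gfr <- convert_units(gfr_ml_min, "mL/min", "L/h")
  s_ua_base <- convert_units(s_ua_base_mg_dl, "mg/dL", "mg/L")
  if (is.null(kp0)) {
    x_ua <- gfr * fe0 * s_ua_base
    kp0 <- baseline_production_rate(s_ua_base, x_ua, cl_i)
  }
  phys <- structure(
    list(gfr = gfr, fe0 = fe0, kp0 = kp0, v_ua = v_ua, cl_i = cl_i,
         s_ua_base = s_ua_base),
    class = "physiology_state"
  )
  validate_physiology_state(phys)
}

validate_physiology_state <- function(phys) {
  fields <- c("gfr", "fe0", "kp0", "v_ua", "cl_i", "s_ua_base")
  for (f in fields) {
    v <- phys[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("physiology_state field '", f, "' must be a finite numeric scalar",
           call. = FALSE)
    }
    if (v <= 0) {
      stop("physiology_state field '", f, "' must be strictly positive (got ",
           format(v), ")", call. = FALSE)
    }
  }
  if (phys$fe0 > 1) {
    stop("physiology_state field 'fe0' must not exceed 1 (got ",
         format(phys$fe0), ")", call. = FALSE)
  }
  phys
}

#' @export
print.physiology_state <- function(x, ...) {
  cat("Uric acid physiology state\n")
  cat(sprintf("  GFR:            %.3f L/h (%.1f mL/min)\n",
              x$gfr, convert_units(x$gfr, "L/h", "mL/min")))
  cat(sprintf("  FE,0:           %.4f\n", x$fe0))
  cat(sprintf("  kP,0:           %.3f mg/h\n", x$kp0))
  cat(sprintf("  V_UA:           %.2f L\n", x$v_ua))
  cat(sprintf("  CL_I:           %.3f L/h\n", x$cl_i))
  cat(sprintf("  baseline sUA:   %.1f mg/L (%.2f mg/dL)\n",
              x$s_ua_base, convert_units(x$s_ua_base, "mg/L", "mg/dL")))
  invisible(x)
}
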