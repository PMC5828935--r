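#' Specification of a treatment-planning nomogram
#'
#' A nomogram maps combinations of production-rate inhibition and
#' fractional-excretion increase to steady-state percent changes in
#' serum uric acid and urinary excretion, for one patient "parametype"
#' (baseline serum uric acid, GFR, baseline fractional excretion). The
#' production rate is back-calculated from the baseline concentration,
#' so the baseline is an input, not a consequence, of the grid.
#'
#' @param base_s_ua_mg_dl baseline serum uric acid, mg/dL.
#' @param gfr_ml_min GFR, mL/min.
#' @param fe0 baseline fractional excretion coefficient.
#' @param cl_i central intestinal clearance, L/h.
#' @param cl_i_range length-2 plausible range of `cl_i` for sensitivity
#'   bands (default the 95 percent CI of the clinical estimate,
#'   0.19-0.36 L/h).
#' @param inhibition grid of fractional production-rate inhibitions,
#'   in \[0, 1).
#' @param increment grid of fractional-excretion increments;
#'   `fe0 + max(increment)` must not exceed 1.
#' @param targets target fractional serum uric acid reductions.
#' @return object of class `nomogram_spec`.
#' @export
nomogram_spec <- function(base_s_ua_mg_dl = 12, gfr_ml_min = 60,
                          fe0 = 0.03, cl_i = 0.27,
                          cl_i_range = c(0.19, 0.36),
                          inhibition = seq(0, 0.9, length.out = 101),
                          increment = seq(0, 0.15, length.out = 101),
                          targets = c(0.25, 0.5, 0.75)) {
  stopifnot(base_s_ua_mg_dl > 0, gfr_ml_min > 0, fe0 > 0, cl_i > 0,
            length(cl_i_range) == 2L, all(cl_i_range > 0),
            cl_i_range[1] <= cl_i_range[2])
  if (any(inhibition < 0) || any(inhibition >= 1)) {
    stop("inhibition grid must lie in [0, 1)")
  }
  if (any(increment < 0) || fe0 + max(increment) > 1) {
    stop("fe0 + max(increment) must not exceed 1")
  }
  structure(list(base_s_ua_mg_dl = base_s_ua_mg_dl,
                 gfr_ml_min = gfr_ml_min, fe0 = fe0, cl_i = cl_i,
                 cl_i_range = cl_i_range, inhibition = sort(inhibition),
                 increment = sort(increment), targets = targets),
            class = "nomogram_spec")
}

nomogram_phys <- function(spec, cl_i = spec$cl_i) {
  physiology_state(spec$gfr_ml_min, spec$fe0, spec$base_s_ua_mg_dl,
                   cl_i = cl_i)
}

#' Build the nomogram grid
#'
#' Evaluates the steady-state serum and urine percent changes on the
#' full (inhibition x increment) grid. The serum change has the closed
#' form
#' \deqn{\frac{[S]}{[S]_0} - 1 =
#'   (1 - i)\,\frac{CL_I + GFR\,F_{E,0}}{CL_I + GFR\,(F_{E,0} + \Delta F_E)} - 1}
#' and the urine change follows from the steady-state excretion rate.
#'
#' @param spec a [nomogram_spec()].
#' @param cl_i intestinal clearance used for the grid; defaults to the
#'   central value.
#' @return object of class `nomogram_grid`: list with `serum_pct` and
#'   `urine_pct` matrices (rows = inhibition, cols = increment, percent
#'   change from baseline), plus the axes.
#' @examples
#' g <- build_grid(nomogram_spec())
#' g$serum_pct["0.5", "0"]  # -50: halving production halves serum UA
#' @export
build_grid <- function(spec, cl_i = spec$cl_i) {
  stopifnot(inherits(spec, "nomogram_spec"))
  phys <- nomogram_phys(spec, cl_i)
  base <- steady_state(phys)
  serum <- outer(spec$inhibition, spec$increment, function(i, d) {
    kp <- phys$kp0 * (1 - i)
    fe <- phys$fe0 + d
    (kp / (phys$cl_i + phys$gfr * fe)) / base$conc - 1
  })
  urine <- outer(spec$inhibition, spec$increment, function(i, d) {
    kp <- phys$kp0 * (1 - i)
    fe <- phys$fe0 + d
    (kp * phys$gfr * fe / (phys$cl_i + phys$gfr * fe)) / base$x_ua - 1
  })
  dimnames(serum) <- dimnames(urine) <-
    list(format(spec$inhibition, trim = TRUE),
         format(spec$increment, trim = TRUE))
  structure(list(serum_pct = 100 * serum, urine_pct = 100 * urine,
                 inhibition = spec$inhibition, increment = spec$increment,
                 spec = spec, cl_i = cl_i),
            class = "nomogram_grid")
}

#' @export
print.nomogram_grid <- function(x, ...) {
  cat(sprintf(
    "Nomogram grid %dx%d (inhibition x FE increment), CL_I = %.2f L/h\n",
    length(x$inhibition), length(x$increment), x$cl_i))
  invisible(x)
}

#' Required production-rate inhibition for a target serum reduction
#'
#' Closed-form solution of the steady state for the fractional
#' production inhibition achieving a target serum uric acid reduction
#' when the fractional excretion coefficient is simultaneously raised by
#' `fe_increment`:
#' \deqn{i = 1 - (1 - r)\,
#'   \frac{CL_I + GFR\,(F_{E,0} + \Delta F_E)}{CL_I + GFR\,F_{E,0}}}
#' floored at 0 (a sufficient uricosuric effect needs no inhibitor).
#'
#' @param target_reduction target fractional serum reduction, in (0, 1).
#' @param fe_increment fractional-excretion increment (\eqn{\ge 0}).
#' @param spec a [nomogram_spec()].
#' @param cl_i intestinal clearance; defaults to the central value.
#' @return required fractional inhibition, in \[0, 1).
#' @examples
#' spec <- nomogram_spec()              # 12 mg/dL, GFR 60, FE 0.03
#' required_inhibition(0.5, 0, spec)    # 0.5
#' required_inhibition(0.5, 0.05, spec) # ~0.26
#' @export
required_inhibition <- function(target_reduction, fe_increment, spec,
                                cl_i = spec$cl_i) {
  stopifnot(inherits(spec, "nomogram_spec"))
  if (any(target_reduction <= 0) || any(target_reduction >= 1)) {
    stop("target_reduction must lie in (0, 1)")
  }
  if (any(fe_increment < 0)) stop("fe_increment must be non-negative")
  gfr <- convert_units(spec$gfr_ml_min, "mL/min", "L/h")
  ratio <- (cl_i + gfr * (spec$fe0 + fe_increment)) / (cl_i + gfr * spec$fe0)
  pmax(1 - (1 - target_reduction) * ratio, 0)
}

#' Urinary excretion at a grid point
#'
#' Steady-state daily urinary uric acid excretion under a combination of
#' production inhibition and fractional-excretion increase, with the
#' production rate anchored to the baseline serum concentration.
#'
#' @param inhibition fractional production inhibition, in \[0, 1).
#' @param increment fractional-excretion increment.
#' @param spec a [nomogram_spec()].
#' @param cl_i intestinal clearance; defaults to the central value.
#' @return named vector `c(mg_24h = , pct_change = )`: daily amount and
#'   percent change versus the untreated baseline.
#' @examples
#' urine_excretion_at(0.26, 0.05, nomogram_spec())  # ~416 mg/24h
#' @export
urine_excretion_at <- function(inhibition, increment, spec,
                               cl_i = spec$cl_i) {
  stopifnot(inherits(spec, "nomogram_spec"))
  phys <- nomogram_phys(spec, cl_i)
  base <- steady_state(phys)
  on <- steady_state(phys, kp = phys$kp0 * (1 - inhibition),
                     fe = phys$fe0 + increment)
  c(mg_24h = on$x_ua * 24, pct_change = 100 * (on$x_ua / base$x_ua - 1))
}

#' Sensitivity of the nomogram to intestinal clearance
#'
#' Recomputes the required inhibition and the daily urinary excretion at
#' the endpoints of the plausible intestinal-clearance range and returns
#' the min/max envelopes around the central values. Because the
#' production rate is re-derived from the baseline serum concentration
#' at each clearance value, the steady-state urinary excretion is
#' insensitive to intestinal clearance — only the required inhibition
#' carries a band, and it is widest at low baseline fractional
#' excretion, where intestinal clearance dominates total clearance.
#'
#' @param spec a [nomogram_spec()] with a non-degenerate `cl_i_range`.
#' @param target_reduction target fractional serum reduction.
#' @param fe_increment fractional-excretion increment (vectorised).
#' @return data frame with one row per increment: `increment`,
#'   `inhibition` (central), `inhibition_lo`, `inhibition_hi`,
#'   `urine_mg_24h` (central), `urine_lo`, `urine_hi`.
#' @export
sensitivity_band <- function(spec, target_reduction = 0.5,
                             fe_increment = spec$increment) {
  stopifnot(inherits(spec, "nomogram_spec"))
  cls <- c(spec$cl_i, spec$cl_i_range)
  inh <- sapply(cls, function(cl)
    required_inhibition(target_reduction, fe_increment, spec, cl_i = cl))
  inh <- matrix(inh, ncol = 3L)
  # urine at each clearance variant's own required inhibition: the amount
  # excreted on target is (1 - r) x conc0 x GFR x FE, free of CL_I
  u <- vapply(seq_len(3L), function(j)
    vapply(seq_along(fe_increment), function(k)
      urine_excretion_at(inh[k, j], fe_increment[k], spec,
                         cl_i = cls[j])[["mg_24h"]],
      numeric(1)),
    numeric(length(fe_increment)))
  u <- matrix(u, ncol = 3L)
  data.frame(
    increment = fe_increment,
    inhibition = inh[, 1],
    inhibition_lo = pmin(inh[, 1], inh[, 2], inh[, 3]),
    inhibition_hi = pmax(inh[, 1], inh[, 2], inh[, 3]),
    urine_mg_24h = u[, 1],
    urine_lo = pmin(u[, 1], u[, 2], u[, 3]),
    urine_hi = pmax(u[, 1], u[, 2], u[, 3])
  )
}
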