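#' Interpolate baseline physiology against GFR
#'
#' For qualification in renally impaired cohorts, per-subject baseline
#' values of the fractional excretion coefficient and production rate
#' are interpolated against GFR (mL/min) with the nonlinear regression
#' form \eqn{\alpha + \beta e^{\gamma \cdot GFR}}. When the exponential
#' does not improve the residual sum of squares over a constant by more
#' than 1 percent (or the fit degenerates), a constant model is selected
#' — some cohorts show no GFR dependence of the baseline coefficient.
#'
#' @param gfr_ml_min per-subject GFR values, mL/min (at least 4, spanning
#'   a range).
#' @param values per-subject target values (baseline fractional
#'   excretion or production rate).
#' @param target `"fe0"` or `"kp0"` (recorded in the result).
#' @return object of class `gfr_interpolation`: list with `form`
#'   (`"exponential"` or `"constant"`), `coef` (named `alpha`, `beta`,
#'   `gamma` for the exponential; `alpha` for the constant), `target`
#'   and `range` (fitted GFR range).
#' @examples
#' gfr <- seq(20, 160, length.out = 12)
#' fe <- 0.06 + 0.15 * exp(-0.06 * gfr)
#' fit <- fit_gfr_interpolation(gfr, fe, "fe0")
#' predict(fit, 50)   # ~0.0675
#' @export
fit_gfr_interpolation <- function(gfr_ml_min, values, target = c("fe0", "kp0")) {
  target <- match.arg(target)
  if (length(gfr_ml_min) < 4L) stop("at least 4 subjects are required")
  if (length(gfr_ml_min) != length(values)) {
    stop("gfr and value vectors must have equal length")
  }
  if (diff(range(gfr_ml_min)) <= 0) stop("GFR values must span a range")
  sse_const <- sum((values - mean(values))^2)
  dat <- data.frame(g = gfr_ml_min, y = values)
  # seed gamma from the half-range decay; try both signs
  fits <- list()
  for (g0 in c(-2 / diff(range(gfr_ml_min)), 2 / diff(range(gfr_ml_min)))) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ alpha + beta * exp(gamma * g), data = dat,
        start = list(alpha = mean(values),
                     beta = values[which.min(gfr_ml_min)] - mean(values),
                     gamma = g0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits <- c(fits, list(f))
  }
  if (length(fits)) {
    sse <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
    bestfit <- fits[[which.min(sse)]]
    improves <- min(sse) < sse_const * (1 - 0.01)
    degenerate <- abs(stats::coef(bestfit)[["gamma"]]) >
      50 / diff(range(gfr_ml_min))
    if (improves && !degenerate) {
      return(structure(list(form = "exponential",
                            coef = stats::coef(bestfit),
                            target = target, range = range(gfr_ml_min)),
                       class = "gfr_interpolation"))
    }
    if (improves && degenerate) {
      warning("exponential GFR interpolation degenerated; using constant",
              call. = FALSE)
    }
  }
  structure(list(form = "constant", coef = c(alpha = mean(values)),
                 target = target, range = range(gfr_ml_min)),
            class = "gfr_interpolation")
}

#' @export
predict.gfr_interpolation <- function(object, gfr_ml_min, ...) {
  g <- gfr_ml_min
  if (any(g < object$range[1] - 1e-9) || any(g > object$range[2] + 1e-9)) {
    stop("GFR outside the fitted interpolation range [",
         object$range[1], ", ", object$range[2], "] mL/min", call. = FALSE)
  }
  if (object$form == "constant") {
    rep(object$coef[["alpha"]], length(g))
  } else {
    object$coef[["alpha"]] + object$coef[["beta"]] *
      exp(object$coef[["gamma"]] * g)
  }
}

#' @export
print.gfr_interpolation <- function(x, ...) {
  cat(sprintf("GFR interpolation of %s (%s): %s\n", x$target, x$form,
              paste(sprintf("%s = %.4g", names(x$coef), x$coef),
                    collapse = ", ")))
  invisible(x)
}

#' Predict 24-h response for a renally impaired subject
#'
#' Builds the subject's baseline physiology from GFR interpolations,
#' drives the fractional excretion coefficient with a spline over the
#' subject's observed drug concentrations, simulates serum and urine
#' uric acid over 24 h and returns the relative changes from baseline.
#'
#' @param gfr_ml_min the subject's pretreatment GFR, mL/min.
#' @param interp_fe0,interp_kp0 [fit_gfr_interpolation()] results for the
#'   baseline fractional excretion coefficient and production rate
#'   (mg/h).
#' @param conc_times,concs observed drug concentration series (h, ng/mL)
#'   spanning at least 24 h.
#' @param rin_params a [reabsorption_inhibitor()] for the drug.
#' @param v_ua,cl_i distribution volume (L) and intestinal clearance
#'   (L/h) used for all subjects.
#' @return named vector from [relative_change_24h()]:
#'   `c(serum = , urine = , fe = )`.
#' @export
predict_renal_subject <- function(gfr_ml_min, interp_fe0, interp_kp0,
                                  conc_times, concs, rin_params,
                                  v_ua = 19, cl_i = 0.27) {
  stopifnot(inherits(interp_fe0, "gfr_interpolation"),
            inherits(interp_kp0, "gfr_interpolation"),
            inherits(rin_params, "reabsorption_inhibitor"))
  if (max(conc_times) < 24) stop("concentration series must span 24 h")
  fe0 <- predict(interp_fe0, gfr_ml_min)
  kp0 <- predict(interp_kp0, gfr_ml_min)
  if (fe0 <= 0 || fe0 >= 1) stop("interpolated FE,0 outside (0, 1)")
  if (kp0 <= 0) stop("interpolated kP,0 must be positive")
  gfr <- convert_units(gfr_ml_min, "mL/min", "L/h")
  conc0 <- kp0 / (cl_i + gfr * fe0)
  phys <- structure(list(gfr = gfr, fe0 = fe0, kp0 = kp0, v_ua = v_ua,
                         cl_i = cl_i, s_ua_base = conc0),
                    class = "physiology_state")
  profile <- interpolate_observed_concentrations(conc_times, concs)
  plan <- simulation_plan(
    phys, rin = list(profile = profile, params = rin_params),
    serum_times = seq(0, 24, by = 2), horizon = 24)
  relative_change_24h(run_simulation(plan))
}

#' A hyperuricemic Phase-III-style subject record
#'
#' @param id subject identifier.
#' @param base_s_ua_mg_dl baseline serum uric acid, mg/dL.
#' @param gfr_ml_min baseline GFR, mL/min.
#' @param fe0 baseline fractional excretion coefficient.
#' @param fe_on measured on-treatment fractional excretion coefficient.
#' @param s_ua_on_mg_dl observed mean on-treatment serum uric acid,
#'   mg/dL.
#' @param allopurinol logical: receiving background allopurinol (the
#'   oxypurinol-interaction correction applies).
#' @return object of class `phase3_subject`.
#' @export
phase3_subject <- function(id, base_s_ua_mg_dl, gfr_ml_min, fe0, fe_on,
                           s_ua_on_mg_dl, allopurinol = FALSE) {
  structure(list(id = id, base_s_ua_mg_dl = base_s_ua_mg_dl,
                 gfr_ml_min = gfr_ml_min, fe0 = fe0, fe_on = fe_on,
                 s_ua_on_mg_dl = s_ua_on_mg_dl,
                 allopurinol = isTRUE(allopurinol)),
            class = "phase3_subject")
}

#' Filter a Phase-III cohort for qualification
#'
#' Retains subjects whose on-treatment serum uric acid decreased from
#' baseline (rising values are a proxy for non-compliance) *and* whose
#' fractional excretion coefficient increased (a decrease is a proxy for
#' measurement error). Subjects with missing fields are excluded as
#' incomplete.
#'
#' @param subjects list of [phase3_subject()] records.
#' @return list with `retained` (subject list) and `exclusions` (named
#'   counts: `incomplete`, `sua_not_decreased`, `fe_not_increased`).
#' @export
filter_phase3_subjects <- function(subjects) {
  reasons <- c(incomplete = 0L, sua_not_decreased = 0L, fe_not_increased = 0L)
  retained <- list()
  for (s in subjects) {
    stopifnot(inherits(s, "phase3_subject"))
    need <- c("base_s_ua_mg_dl", "gfr_ml_min", "fe0", "fe_on",
              "s_ua_on_mg_dl")
    vals <- unlist(s[need])
    if (any(is.na(vals)) || !all(is.finite(vals))) {
      reasons["incomplete"] <- reasons["incomplete"] + 1L
      next
    }
    if (s$s_ua_on_mg_dl >= s$base_s_ua_mg_dl) {
      reasons["sua_not_decreased"] <- reasons["sua_not_decreased"] + 1L
      next
    }
    if (s$fe_on <= s$fe0) {
      reasons["fe_not_increased"] <- reasons["fe_not_increased"] + 1L
      next
    }
    retained <- c(retained, list(s))
  }
  list(retained = retained, exclusions = reasons)
}

#' Predicted relative change in serum uric acid for a Phase-III subject
#'
#' The individual steady-state prediction used to qualify the model in
#' hyperuricemic patients: the production rate is back-calculated from
#' the subject's baseline (GFR, baseline fractional excretion, baseline
#' serum uric acid, common intestinal clearance); the on-treatment serum
#' uric acid is the steady state at the *measured* on-treatment
#' fractional excretion; the prediction is the relative change. For
#' subjects on background allopurinol the prediction is corrected for
#' the lesinurad-oxypurinol interaction
#' ([oxypurinol_interaction_factor()] at a daily average oxypurinol
#' concentration of 10,000 ng/mL, exposure reduction 0.32).
#'
#' @param subject a [phase3_subject()] (should have passed
#'   [filter_phase3_subjects()]).
#' @param cl_i intestinal clearance, L/h.
#' @param oxy_params [production_inhibitor()] for oxypurinol (used only
#'   when `subject$allopurinol` is set).
#' @param oxy_conc daily average oxypurinol concentration, ng/mL.
#' @param reduction fractional reduction of oxypurinol exposure by
#'   lesinurad.
#' @return predicted relative change in serum uric acid (fraction).
#' @export
predict_phase3_change <- function(subject, cl_i = 0.27,
                                  oxy_params = ua_drug_params("oxypurinol"),
                                  oxy_conc = 10000, reduction = 0.32) {
  stopifnot(inherits(subject, "phase3_subject"))
  gfr <- convert_units(subject$gfr_ml_min, "mL/min", "L/h")
  base_conc <- convert_units(subject$base_s_ua_mg_dl, "mg/dL", "mg/L")
  x_ua0 <- gfr * subject$fe0 * base_conc
  kp <- baseline_production_rate(base_conc, x_ua0, cl_i)
  conc_on <- kp / (cl_i + gfr * subject$fe_on)
  delta <- conc_on / base_conc - 1
  if (subject$allopurinol) {
    fac <- oxypurinol_interaction_factor(oxy_conc, oxy_params, reduction)
    delta <- corrected_relative_change(delta, fac)
  }
  delta
}
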