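#' Emax parameters for a uric acid production inhibitor
#'
#' Parameters of the saturable effect of a xanthine oxidase inhibitor
#' (XOI) on the uric acid production rate: `r_max`, the maximum fractional
#' decrease of the rate, and `p50_pin`, the plasma concentration at
#' half-maximal effect.
#'
#' @param r_max maximum fractional decrease in production rate, in \[0, 1\].
#' @param p50_pin half-maximal plasma concentration, ng/mL (> 0).
#' @param drug optional drug name.
#' @return object of class `production_inhibitor`.
#' @export
production_inhibitor <- function(r_max, p50_pin, drug = NA_character_) {
  if (!is.finite(r_max) || r_max < 0 || r_max > 1) {
    stop("r_max must lie in [0, 1]")
  }
  if (!is.finite(p50_pin) || p50_pin <= 0) stop("p50_pin must be positive")
  structure(list(r_max = r_max, p50_pin = p50_pin, drug = drug),
            class = "production_inhibitor")
}

#' Emax parameters for a uric acid reabsorption inhibitor
#'
#' Parameters of the saturable effect of a uricosuric (URAT1 reabsorption
#' inhibitor) on the fractional excretion coefficient: `f_max`, the
#' maximum additive increase of the coefficient, and `p50_rin`, the
#' plasma concentration at half-maximal effect.
#'
#' @param f_max maximum increase in fractional excretion (\eqn{\ge 0}).
#' @param p50_rin half-maximal plasma concentration, ng/mL (> 0).
#' @param drug optional drug name.
#' @return object of class `reabsorption_inhibitor`.
#' @export
reabsorption_inhibitor <- function(f_max, p50_rin, drug = NA_character_) {
  if (!is.finite(f_max) || f_max < 0) stop("f_max must be non-negative")
  if (!is.finite(p50_rin) || p50_rin <= 0) stop("p50_rin must be positive")
  structure(list(f_max = f_max, p50_rin = p50_rin, drug = drug),
            class = "reabsorption_inhibitor")
}

#' Production rate under a xanthine oxidase inhibitor
#'
#' \deqn{k_P = k_{P,0} \left(1 - \frac{R_{max} [P]}{[P] + [P]_{50}}\right)}
#' The rate at maximal drug effect is \eqn{k_{P,0}(1 - R_{max})}; at
#' \eqn{[P] = [P]_{50}} it is \eqn{k_{P,0}(1 - R_{max}/2)}.
#'
#' @param kp0 drug-free production rate, mg/h.
#' @param params a [production_inhibitor()].
#' @param conc plasma drug concentration(s), ng/mL (\eqn{\ge 0}), vectorised.
#' @return production rate(s), mg/h.
#' @examples
#' oxy <- production_inhibitor(0.84, 14000, "oxypurinol")
#' production_rate_under_drug(45.36, oxy, 10000) / 45.36  # 0.65: 35% decrease
#' @export
production_rate_under_drug <- function(kp0, params, conc) {
  stopifnot(inherits(params, "production_inhibitor"))
  if (any(conc < 0)) stop("drug concentration must be non-negative")
  kp0 * (1 - params$r_max * conc / (conc + params$p50_pin))
}

#' Fractional excretion under a reabsorption inhibitor
#'
#' \deqn{F_E = F_{E,0} + \frac{F_{max} [P]}{[P] + [P]_{50}}}
#' The coefficient at maximal drug effect is \eqn{F_{E,0} + F_{max}}.
#' A configuration whose maximal coefficient exceeds 1 is nonphysical and
#' rejected.
#'
#' @param fe0 drug-free fractional excretion coefficient.
#' @param params a [reabsorption_inhibitor()].
#' @param conc plasma drug concentration(s), ng/mL (\eqn{\ge 0}), vectorised.
#' @return fractional excretion coefficient(s).
#' @examples
#' les <- reabsorption_inhibitor(0.56, 11000, "lesinurad")
#' fe_under_drug(0.07, les, 1e12)  # ~0.63, the model's largest FE
#' @export
fe_under_drug <- function(fe0, params, conc) {
  stopifnot(inherits(params, "reabsorption_inhibitor"))
  if (any(conc < 0)) stop("drug concentration must be non-negative")
  if (fe0 + params$f_max > 1 + 1e-12) {
    stop("fe0 + f_max exceeds 1: nonphysical fractional excretion configuration")
  }
  fe0 + params$f_max * conc / (conc + params$p50_rin)
}

#' Serum uric acid inflation ratio from reduced oxypurinol exposure
#'
#' Lesinurad co-administration lowers daily average oxypurinol
#' concentration (by 32 percent at 200-400 mg lesinurad with 300 mg
#' allopurinol). Because steady-state serum uric acid is proportional to
#' the production rate, the resulting inflation of serum uric acid
#' relative to the uncorrected prediction is
#' \deqn{\frac{1 - R_{max}\,(1-r)[P] / ((1-r)[P] + [P]_{50})}
#'            {1 - R_{max}\,[P] / ([P] + [P]_{50})}}
#' where \eqn{r} is the fractional reduction in oxypurinol exposure.
#'
#' @param p_pin daily average oxypurinol concentration without lesinurad,
#'   ng/mL.
#' @param params a [production_inhibitor()] for oxypurinol.
#' @param reduction fractional reduction of oxypurinol exposure, in
#'   \[0, 1); default 0.32.
#' @return scalar ratio (\eqn{\ge 1} for an active inhibitor).
#' @examples
#' oxy <- production_inhibitor(0.84, 14000)
#' oxypurinol_interaction_factor(10000, oxy)  # ~1.116
#' @export
oxypurinol_interaction_factor <- function(p_pin, params, reduction = 0.32) {
  stopifnot(inherits(params, "production_inhibitor"))
  if (reduction < 0 || reduction >= 1) stop("reduction must lie in [0, 1)")
  if (p_pin < 0) stop("oxypurinol concentration must be non-negative")
  p_red <- (1 - reduction) * p_pin
  num <- 1 - params$r_max * p_red / (p_red + params$p50_pin)
  den <- 1 - params$r_max * p_pin / (p_pin + params$p50_pin)
  num / den
}

#' Apply the oxypurinol-interaction correction to a predicted change
#'
#' Converts a predicted relative change in serum uric acid into the
#' corrected change accounting for the interaction factor:
#' \deqn{\Delta_{corr} = factor \times (\Delta_{pred} + 1) - 1}
#'
#' @param delta_pred predicted relative change in serum uric acid
#'   (fraction, \eqn{\ge -1}).
#' @param factor interaction ratio from
#'   [oxypurinol_interaction_factor()].
#' @return corrected relative change (fraction).
#' @export
corrected_relative_change <- function(delta_pred, factor) {
  if (any(delta_pred < -1)) stop("relative change cannot be below -1")
  factor * (delta_pred + 1) - 1
}

#' Default drug-effect parameter sets
#'
#' The drug-effect parameters shipped with the package, estimated from
#' Phase I data of lesinurad alone and in combination with allopurinol or
#' febuxostat: oxypurinol (allopurinol's active metabolite) and
#' febuxostat act as production inhibitors, lesinurad as a reabsorption
#' inhibitor. Half-maximal concentrations for febuxostat and lesinurad
#' were estimated separately for gout subjects with hyperuricemia; the
#' `hyperuricemic` flag selects that variant.
#'
#' @param drug `"oxypurinol"`, `"febuxostat"` or `"lesinurad"`.
#' @param hyperuricemic logical; use the hyperuricemic-subject
#'   half-maximal concentration where one exists.
#' @return a [production_inhibitor()] or [reabsorption_inhibitor()].
#' @examples
#' ua_drug_params("oxypurinol")            # Rmax 0.84, P50 14000
#' ua_drug_params("lesinurad", TRUE)       # Fmax 0.56, P50 23000
#' @export
ua_drug_params <- function(drug = c("oxypurinol", "febuxostat", "lesinurad"),
                           hyperuricemic = FALSE) {
  drug <- match.arg(drug)
  switch(drug,
    oxypurinol = production_inhibitor(0.84, 14000, "oxypurinol"),
    febuxostat = production_inhibitor(
      1, if (hyperuricemic) 120 else 87, "febuxostat"),
    lesinurad = reabsorption_inhibitor(
      0.56, if (hyperuricemic) 23000 else 11000, "lesinurad")
  )
}

#' Default residual-error models
#'
#' Combined additive-proportional residual error parameters for the two
#' observation streams, as estimated from the Phase I data: serum uric
#' acid concentration (additive SD 0.45 mg/dL = 4.5 mg/L, proportional SD
#' 0.15) and urine-interval uric acid amount (additive SD 50 mg,
#' proportional SD 0.29). Serum values are expressed in the internal
#' mg/L scale.
#'
#' @return named list with [error_model()] objects `serum` and `urine`.
#' @export
ua_error_defaults <- function() {
  list(serum = error_model(a = 4.5, b = 0.15),
       urine = error_model(a = 50, b = 0.29))
}
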