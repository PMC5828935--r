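#' Convert between the unit pairs used at the package boundaries
#'
#' The package works internally in mg, L and h. Clinical data arrive in
#' mg/dL (serum uric acid), mL/min (creatinine clearance / GFR) and
#' mg/24h (daily urinary excretion); this helper performs the exact
#' factor conversions between those representations.
#'
#' Supported pairs: `mg/dL` \eqn{\leftrightarrow}{<->} `mg/L` (factor 10),
#' `mL/min` \eqn{\leftrightarrow}{<->} `L/h` (factor 0.06) and
#' `mg/h` \eqn{\leftrightarrow}{<->} `mg/24h` (factor 24).
#'
#' @param value numeric vector to convert.
#' @param from,to unit strings, e.g. `"mg/dL"`, `"mg/L"`, `"mL/min"`,
#'   `"L/h"`, `"mg/h"`, `"mg/24h"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_units(12, "mg/dL", "mg/L")   # 120
#' convert_units(60, "mL/min", "L/h")   # 3.6
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), is.character(from), is.character(to))
  if (identical(from, to)) return(value)
  factors <- list(
    "mg/dL->mg/L"   = 10,
    "mg/L->mg/dL"   = 0.1,
    "mL/min->L/h"   = 0.06,
    "L/h->mL/min"   = 1 / 0.06,
    "mg/h->mg/24h"  = 24,
    "mg/24h->mg/h"  = 1 / 24
  )
  key <- paste0(from, "->", to)
  f <- factors[[key]]
  if (is.null(f)) {
    stop("unsupported unit conversion: ", from, " -> ", to, call. = FALSE)
  }
  value * f
}

#' Cockcroft-Gault creatinine clearance
#'
#' Standard Cockcroft-Gault estimate of creatinine clearance from age,
#' actual body weight and serum creatinine, used as the GFR approximation
#' throughout the package:
#' \deqn{CrCl = \frac{(140 - age) \times weight}{72 \times SCr}
#'   \; (\times\, 0.85 \ \mathrm{if\ female})}
#'
#' @param age years.
#' @param weight actual body weight, kg.
#' @param scr serum creatinine, mg/dL.
#' @param sex `"male"` or `"female"`.
#' @return creatinine clearance in mL/min.
#' @examples
#' cockcroft_gault(40, 72, 1.0, "male")    # 100
#' cockcroft_gault(40, 72, 1.0, "female")  # 85
#' @export
cockcroft_gault <- function(age, weight, scr, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (any(!is.finite(age)) || any(age < 0)) stop("age must be finite and non-negative")
  if (any(age >= 140)) stop("age must be below 140 years for Cockcroft-Gault")
  if (any(weight < 0)) stop("weight must be non-negative")
  if (any(scr <= 0)) stop("serum creatinine must be positive")
  crcl <- (140 - age) * weight / (72 * scr)
  if (sex == "female") crcl <- crcl * 0.85
  crcl
}
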