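#' Combined additive-proportional residual error model
#'
#' Observations are modelled as
#' \deqn{y = f + \sqrt{a^2 + (b f)^2}\,\varepsilon, \qquad
#'       \varepsilon \sim N(0, 1)}
#' where \eqn{f} is the model prediction, `a` the additive standard
#' deviation (units of the observation) and `b` the proportional
#' standard deviation. The prediction (not the observation) enters the
#' variance.
#'
#' @param a additive SD (\eqn{\ge 0}).
#' @param b proportional SD (\eqn{\ge 0}); `a` and `b` not both zero.
#' @return object of class `error_model`.
#' @export
error_model <- function(a, b) {
  if (a < 0 || b < 0) stop("error SDs must be non-negative")
  if (a == 0 && b == 0) stop("error model must have a non-zero component")
  structure(list(a = a, b = b), class = "error_model")
}

error_sd <- function(em, f) sqrt(em$a^2 + (em$b * f)^2)

#' One treatment group of a (synthetic) multi-group trial
#'
#' Holds the group-mean observations and covariates for one treatment
#' group: baseline physiology measured predose (GFR, baseline fractional
#' excretion, baseline serum uric acid), the drug exposures, and the
#' serum/urine observation series. Drug-effect parameters are referenced
#' by *name* (e.g. `"p50_oxypurinol"`), which the fit resolves against
#' the current parameter vector — this is how half-maximal concentrations
#' can differ between hyperuricemic and non-hyperuricemic groups.
#'
#' @param id group identifier.
#' @param gfr_ml_min group-mean GFR, mL/min.
#' @param fe0 group-mean baseline fractional excretion coefficient.
#' @param base_s_ua_mg_dl group-mean predose serum uric acid, mg/dL.
#' @param serum data frame `time` (h), `value` (mg/L) of serum uric acid
#'   observations.
#' @param urine data frame `start`, `end` (h), `value` (mg) of
#'   urine-interval amounts.
#' @param pin optional production-inhibitor exposure:
#'   `list(profile = concentration_profile, r_max_name = , p50_name = )`.
#' @param rin optional reabsorption-inhibitor exposure:
#'   `list(profile = concentration_profile, f_max_name = , p50_name = )`.
#' @param hyperuricemic logical flag (used when constructing parameter
#'   names, and reported in summaries).
#' @return object of class `treatment_group`.
#' @export
treatment_group <- function(id, gfr_ml_min, fe0, base_s_ua_mg_dl,
                            serum, urine, pin = NULL, rin = NULL,
                            hyperuricemic = FALSE) {
  stopifnot(is.data.frame(serum), all(c("time", "value") %in% names(serum)),
            is.data.frame(urine),
            all(c("start", "end", "value") %in% names(urine)))
  if (nrow(serum) < 1L || nrow(urine) < 1L) {
    stop("each fitted group needs at least one serum and one urine observation")
  }
  structure(list(
    id = id,
    gfr = convert_units(gfr_ml_min, "mL/min", "L/h"),
    fe0 = fe0,
    base_conc = convert_units(base_s_ua_mg_dl, "mg/dL", "mg/L"),
    serum = serum, urine = urine,
    pin = pin, rin = rin,
    hyperuricemic = isTRUE(hyperuricemic)
  ), class = "treatment_group")
}

#' Specification of a model fit
#'
#' Declares which parameters are estimated (with initial values and
#' optional box bounds) and which are fixed. Parameter names follow the
#' convention `cl_i`, `v_ua`, `r_max_<drug>`, `p50_<drug>` (append
#' `_hyper` for hyperuricemic-group variants), `f_max_<drug>`, and the
#' residual error SDs `a_serum`, `b_serum`, `a_urine`, `b_urine`. Every
#' name referenced by a fitted [treatment_group()] must appear in either
#' `free` or `fixed`.
#'
#' @param free named numeric vector of initial values for estimated
#'   parameters (all strictly positive; estimation is on the log scale).
#' @param fixed named numeric vector of fixed parameter values.
#' @param lower,upper optional named vectors of box bounds (natural
#'   scale) for a subset of the free parameters.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(free, fixed = numeric(0),
                     lower = numeric(0), upper = numeric(0)) {
  if (is.null(names(free)) || any(!nzchar(names(free)))) {
    stop("free parameters must be named")
  }
  if (any(free <= 0)) stop("free parameter initial values must be positive")
  if (any(names(free) %in% names(fixed))) {
    stop("a parameter cannot be both free and fixed: ",
         paste(intersect(names(free), names(fixed)), collapse = ", "))
  }
  for (req in c("cl_i", "v_ua", "a_serum", "b_serum", "a_urine", "b_urine")) {
    if (!req %in% c(names(free), names(fixed))) {
      stop("parameter '", req, "' must be declared free or fixed")
    }
  }
  structure(list(free = free, fixed = fixed, lower = lower, upper = upper),
            class = "fit_spec")
}

resolve_params <- function(params, spec) {
  theta <- c(params, spec$fixed)
  theta[!duplicated(names(theta))]
}

# model predictions for one group at a full named parameter vector
group_predictions <- function(group, theta) {
  cl_i <- theta[["cl_i"]]
  v_ua <- theta[["v_ua"]]
  # baseline production rate recomputed from the current CL_I iterate;
  # X_UA,0 comes from the measured baseline via the FE,0 relation
  x_ua0 <- group$gfr * group$fe0 * group$base_conc
  kp0 <- baseline_production_rate(group$base_conc, x_ua0, cl_i)
  phys <- structure(list(gfr = group$gfr, fe0 = group$fe0, kp0 = kp0,
                         v_ua = v_ua, cl_i = cl_i,
                         s_ua_base = group$base_conc),
                    class = "physiology_state")
  pin <- if (!is.null(group$pin)) {
    list(profile = group$pin$profile,
         params = production_inhibitor(theta[[group$pin$r_max_name]],
                                       theta[[group$pin$p50_name]]))
  }
  rin <- if (!is.null(group$rin)) {
    list(profile = group$rin$profile,
         params = reabsorption_inhibitor(theta[[group$rin$f_max_name]],
                                         theta[[group$rin$p50_name]]))
  }
  horizon <- max(group$serum$time, group$urine$end)
  ui <- unique(cbind(group$urine$start, group$urine$end))
  plan <- simulation_plan(phys, pin = pin, rin = rin,
                          serum_times = unique(group$serum$time),
                          urine_intervals = ui,
                          horizon = horizon)
  res <- run_simulation(plan, n_grid = 2L, method = "exponential",
                        h_exp = 0.05)
  f_serum <- res$serum_obs$conc[match(group$serum$time, res$serum_obs$time)]
  key <- paste(group$urine$start, group$urine$end)
  f_urine <- res$urine$amount[match(key, paste(res$urine$start, res$urine$end))]
  list(serum = f_serum, urine = f_urine)
}

#' Negative log-likelihood of the uric acid model
#'
#' Gaussian negative log-likelihood under the combined error model,
#' summed over all serum and urine observations of all groups. Serum and
#' urine streams use their own `(a, b)`. The baseline production rate of
#' each group is recomputed from the current intestinal clearance before
#' prediction, keeping each group's predose steady state anchored to its
#' measured baseline.
#'
#' @param params named numeric vector of free parameter values (natural
#'   scale).
#' @param groups list of [treatment_group()] objects.
#' @param spec a [fit_spec()].
#' @return scalar negative log-likelihood. Non-finite predictions yield a
#'   large penalised value with a warning rather than an error.
#' @export
neg_log_likelihood <- function(params, groups, spec) {
  theta <- resolve_params(params, spec)
  em_serum <- error_model(theta[["a_serum"]], theta[["b_serum"]])
  em_urine <- error_model(theta[["a_urine"]], theta[["b_urine"]])
  nll <- 0
  for (g in groups) {
    f <- tryCatch(group_predictions(g, theta), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(c(f$serum, f$urine)))) {
      warning("non-finite model prediction for group '", g$id,
              "': objective penalised", call. = FALSE)
      return(1e10)
    }
    nll <- nll + gauss_nll(g$serum$value, f$serum, em_serum) +
      gauss_nll(g$urine$value, f$urine, em_urine)
  }
  nll
}

gauss_nll <- function(y, f, em) {
  sd <- error_sd(em, f)
  sum(0.5 * log(2 * pi) + log(sd) + 0.5 * ((y - f) / sd)^2)
}

#' Maximum-likelihood fit of the uric acid model
#'
#' Minimises [neg_log_likelihood()] over the free parameters of the
#' specification. Drug concentration inputs must already be attached to
#' the groups (simulated pharmacokinetic profiles or splines over
#' observed concentrations) — estimation is sequential, pharmacokinetics
#' first, uric acid model second. Parameters are estimated on the log
#' scale to enforce positivity: a derivative-free Nelder-Mead search is
#' followed by a quasi-Newton (BFGS) polish. Asymptotic standard errors
#' come from the inverse observed information (finite-difference Hessian
#' of the log-scale objective), transformed to the natural scale by the
#' delta method.
#'
#' @param groups list of [treatment_group()] objects.
#' @param spec a [fit_spec()].
#' @param n_starts number of optimisation starts. Starts beyond the
#'   first perturb the initial values log-uniformly within a factor of 3
#'   (seeded, reproducible).
#' @param control list of optimiser settings: `maxit_nm`, `maxit_bfgs`,
#'   `reltol`, `seed` (for multistart perturbations).
#' @return object of class `ua_fit`: list with `estimates`, `se`,
#'   `rse_pct` (named vectors over free parameters), `objective`,
#'   `convergence` (TRUE if the best start converged), `residuals`
#'   (weighted-residual table from [weighted_residuals()]), `spec` and
#'   `n_obs`.
#' @export
fit_ua_model <- function(groups, spec, n_starts = 1L,
                         control = list()) {
  stopifnot(inherits(spec, "fit_spec"), length(groups) >= 1L)
  ctl <- utils::modifyList(
    list(maxit_nm = 500L * length(spec$free), maxit_bfgs = 100L,
         reltol = 1e-9, seed = 20260101L), control)
  free_names <- names(spec$free)
  lo <- rep(-Inf, length(free_names)); hi <- rep(Inf, length(free_names))
  names(lo) <- names(hi) <- free_names
  lo[names(spec$lower)] <- log(spec$lower)
  hi[names(spec$upper)] <- log(spec$upper)
  obj <- function(lpar) {
    if (any(!is.finite(lpar)) || any(lpar < lo) || any(lpar > hi)) {
      return(1e10)
    }
    p <- exp(lpar)
    if (any(!is.finite(p))) return(1e10)
    names(p) <- free_names
    v <- neg_log_likelihood(p, groups, spec)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(log(spec$free))
  if (n_starts > 1L) {
    rng <- local({
      set.seed(ctl$seed)
      lapply(seq_len(n_starts - 1L), function(i)
        log(spec$free) + stats::runif(length(spec$free), log(1 / 3), log(3)))
    })
    starts <- c(starts, rng)
  }
  best <- NULL
  for (s in starts) {
    nm <- stats::optim(s, obj, method = "Nelder-Mead",
                       control = list(maxit = ctl$maxit_nm,
                                      reltol = ctl$reltol))
    pol <- tryCatch(
      stats::optim(nm$par, obj, method = "BFGS",
                   control = list(maxit = ctl$maxit_bfgs,
                                  reltol = ctl$reltol)),
      error = function(e) nm)
    cand <- if (pol$value <= nm$value) pol else nm
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  converged <- best$convergence == 0 && best$value < 1e9
  if (!converged) {
    warning("optimiser did not converge cleanly; estimates reported anyway",
            call. = FALSE)
  }
  est_log <- best$par
  estimates <- exp(est_log)
  names(estimates) <- free_names
  se_log <- rep(NA_real_, length(free_names))
  hess <- tryCatch(stats::optimHess(est_log, obj), error = function(e) NULL)
  if (!is.null(hess)) {
    cov_log <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov_log)) {
      d <- diag(cov_log)
      se_log <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  se <- estimates * se_log  # delta method for exp()
  names(se) <- free_names
  rse <- 100 * se / abs(estimates)
  theta <- resolve_params(estimates, spec)
  em_serum <- error_model(theta[["a_serum"]], theta[["b_serum"]])
  em_urine <- error_model(theta[["a_urine"]], theta[["b_urine"]])
  res_tab <- do.call(rbind, lapply(groups, function(g) {
    f <- group_predictions(g, theta)
    rbind(
      cbind(weighted_residuals(g$serum$value, f$serum, em_serum),
            data.frame(stream = "serum", time = g$serum$time, group = g$id)),
      cbind(weighted_residuals(g$urine$value, f$urine, em_urine),
            data.frame(stream = "urine",
                       time = (g$urine$start + g$urine$end) / 2,
                       group = g$id))
    )
  }))
  structure(list(estimates = estimates, se = se, rse_pct = rse,
                 objective = best$value, convergence = converged,
                 residuals = res_tab, spec = spec,
                 n_obs = sum(vapply(groups, function(g)
                   nrow(g$serum) + nrow(g$urine), numeric(1)))),
            class = "ua_fit")
}

#' @export
print.ua_fit <- function(x, ...) {
  cat(sprintf("Uric acid model fit (%d observations, -2LL = %.2f, %s)\n",
              x$n_obs, 2 * x$objective,
              if (x$convergence) "converged" else "NOT converged"))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    se = signif(x$se, 3),
                    rse_pct = round(x$rse_pct, 1))
  print(tab)
  invisible(x)
}

#' Weighted residuals
#'
#' Differences between observations and predictions divided by the
#' estimated standard deviation of the measurement error:
#' \deqn{w = \frac{y - f}{\sqrt{a^2 + (b f)^2}}}
#'
#' @param observations observed values.
#' @param predictions model predictions (same length).
#' @param error an [error_model()].
#' @return data frame `observed`, `predicted`, `wres`.
#' @examples
#' weighted_residuals(6.45, 6.0, error_model(0.45, 0.15))  # wres ~ 0.447
#' @export
weighted_residuals <- function(observations, predictions, error) {
  stopifnot(inherits(error, "error_model"),
            length(observations) == length(predictions))
  data.frame(observed = observations, predicted = predictions,
             wres = (observations - predictions) / error_sd(error, predictions))
}

#' Adequacy diagnostics for a fit
#'
#' Applies the adequacy rules used for the clinical fits: every
#' estimated parameter should have a relative standard error below about
#' 30 percent, and weighted residuals should show no systematic trend
#' against time or against the prediction. Trends are screened by
#' binning residuals along the covariate and flagging any bin whose mean
#' deviates from zero by more than `z_crit` standard errors (residuals
#' have unit variance under a correct model).
#'
#' @param fit a [fit_ua_model()] result.
#' @param rse_limit relative-standard-error threshold, percent.
#' @param n_bins number of bins for the trend screen.
#' @param z_crit flag threshold in standard-error units.
#' @return object of class `ua_adequacy`: list with `rse_flags` (names of
#'   parameters at or above the limit), `trend_flags` (character vector
#'   among `"time"`, `"prediction"`), and `pass` (no flags).
#' @export
adequacy_report <- function(fit, rse_limit = 30, n_bins = 5L, z_crit = 3) {
  stopifnot(inherits(fit, "ua_fit"))
  rse_flags <- names(fit$rse_pct)[!is.na(fit$rse_pct) &
                                    fit$rse_pct >= rse_limit]
  trend_flags <- character(0)
  screen <- function(x, w) {
    br <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L))
    br <- unique(br)
    if (length(br) < 3L) return(FALSE)
    bin <- cut(x, br, include.lowest = TRUE)
    means <- tapply(w, bin, mean)
    ns <- tapply(w, bin, length)
    any(abs(means) * sqrt(ns) > z_crit, na.rm = TRUE)
  }
  for (stream in unique(fit$residuals$stream)) {
    r <- fit$residuals[fit$residuals$stream == stream, ]
    if (screen(r$time, r$wres)) trend_flags <- c(trend_flags, "time")
    if (screen(r$predicted, r$wres)) trend_flags <- c(trend_flags, "prediction")
  }
  trend_flags <- unique(trend_flags)
  structure(list(rse_flags = rse_flags, trend_flags = trend_flags,
                 pass = length(rse_flags) == 0L && length(trend_flags) == 0L),
            class = "ua_adequacy")
}

#' @export
print.ua_adequacy <- function(x, ...) {
  cat("Model adequacy:", if (x$pass) "PASS" else "flags raised", "\n")
  if (length(x$rse_flags)) {
    cat("  RSE >= limit:", paste(x$rse_flags, collapse = ", "), "\n")
  }
  if (length(x$trend_flags)) {
    cat("  residual trend vs:", paste(x$trend_flags, collapse = ", "), "\n")
  }
  invisible(x)
}
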