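#' Replicate parameter-recovery study
#'
#' Simulation-based check of the estimation machinery: synthetic
#' multi-group trials are generated at the default parameter truth with
#' the combined residual error, refitted by maximum likelihood, and the
#' recovered estimates compared with the generating values. Two
#' scenarios are available:
#' \describe{
#'   \item{`"multigroup"`}{the default Phase-I-style design (lesinurad
#'     dose range alone and combined with allopurinol or febuxostat);
#'     free parameters are the intestinal clearance, the distribution
#'     volume and the oxypurinol and lesinurad half-maximal
#'     concentrations.}
#'   \item{`"lesinurad_monotherapy"`}{lesinurad-alone groups spanning
#'     50-1600 mg; the maximal fractional-excretion increase and the
#'     half-maximal concentration are fitted jointly.}
#' }
#' Maximal drug effects (`r_max`, and `f_max` outside the monotherapy
#' scenario) and the residual error SDs are held at their known values,
#' mirroring the fixed-parameter handling of the clinical analysis.
#'
#' @param n_replicates number of simulated trials.
#' @param seed base integer seed; replicate `r` uses `seed + 1000 * r`
#'   for its noise streams.
#' @param scenario `"multigroup"` or `"lesinurad_monotherapy"`.
#' @param truth generating parameter vector, default
#'   [ua_param_defaults()].
#' @param control optimiser control passed to [fit_ua_model()].
#' @return data frame with one row per replicate and free parameter:
#'   `replicate`, `parameter`, `estimate`, `se`, `truth`, `covered`
#'   (truth within 2 asymptotic SE), `converged`.
#' @export
ua_recovery_study <- function(n_replicates = 20L, seed = 1L,
                              scenario = c("multigroup",
                                           "lesinurad_monotherapy"),
                              truth = ua_param_defaults(),
                              control = list(reltol = 1e-8)) {
  scenario <- match.arg(scenario)
  if (scenario == "multigroup") {
    design <- phase1_design()
    free <- c(cl_i = 0.4, v_ua = 14, p50_oxypurinol = 20000,
              p50_lesinurad = 6000)
  } else {
    design <- phase1_design(groups = data.frame(
      id = paste0("LSN", c(50, 100, 200, 400, 800, 1600)),
      lesinurad_mg = c(50, 100, 200, 400, 800, 1600),
      xoi = NA_character_, xoi_mg = NA_real_, hyperuricemic = FALSE))
    free <- c(f_max_lesinurad = 0.3, p50_lesinurad = 5000)
  }
  fixed <- truth[setdiff(names(truth), names(free))]
  spec <- fit_spec(free = free, fixed = fixed)
  out <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- seed + 1000L * r
    pop <- sample_population(population_spec(nrow(design$groups)),
                             seed = rep_seed)
    trial <- generate_trial(pop, design, truth = truth, seed = rep_seed)
    fit <- fit_ua_model(trial$groups, spec, control = control)
    out[[r]] <- data.frame(
      replicate = r,
      parameter = names(fit$estimates),
      estimate = unname(fit$estimates),
      se = unname(fit$se),
      truth = unname(truth[names(fit$estimates)]),
      covered = abs(unname(fit$estimates) -
                      unname(truth[names(fit$estimates)])) <=
        2 * unname(fit$se),
      converged = fit$convergence,
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("ua_recovery", class(res))
  res
}

#' Summarise a recovery study
#'
#' @param object a [ua_recovery_study()] result.
#' @param ... unused.
#' @return data frame per parameter: `truth`, `median_estimate`,
#'   `mean_estimate`, `coverage` (fraction of replicates with truth
#'   within 2 asymptotic SE), `n`.
#' @export
summary.ua_recovery <- function(object, ...) {
  sp <- split(object, object$parameter)
  do.call(rbind, lapply(sp, function(d) data.frame(
    parameter = d$parameter[1],
    truth = d$truth[1],
    median_estimate = stats::median(d$estimate),
    mean_estimate = mean(d$estimate),
    coverage = mean(d$covered, na.rm = TRUE),
    n = nrow(d),
    row.names = NULL)))
}
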