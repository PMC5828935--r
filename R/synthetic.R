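#' Model parameter defaults
#'
#' The full named parameter vector used as generating truth by the
#' synthetic-data module and as the shipped defaults elsewhere:
#' intestinal clearance and distribution volume of uric acid, the
#' drug-effect parameters of oxypurinol, febuxostat and lesinurad
#' (hyperuricemic-subject half-maximal concentrations carry the
#' `_hyper` suffix), and the residual error SDs of the serum (mg/L) and
#' urine (mg) observation streams.
#'
#' @return named numeric vector.
#' @export
ua_param_defaults <- function() {
  c(cl_i = 0.27, v_ua = 19,
    r_max_oxypurinol = 0.84, p50_oxypurinol = 14000,
    r_max_febuxostat = 1, p50_febuxostat = 87, p50_febuxostat_hyper = 120,
    f_max_lesinurad = 0.56, p50_lesinurad = 11000,
    p50_lesinurad_hyper = 23000,
    a_serum = 4.5, b_serum = 0.15, a_urine = 50, b_urine = 0.29)
}

#' Stand-in oral PK parameters per drug
#'
#' One-compartment first-order-absorption parameters used to simulate
#' plasma concentration inputs. These are package choices producing
#' realistic exposure scales: lesinurad reaches several thousand ng/mL
#' after a 200 mg dose with a terminal half-life of about 5 h;
#' oxypurinol (dosed as allopurinol-equivalents) has a ~20 h half-life
#' and a daily average near 10,000 ng/mL under repeated 300 mg dosing;
#' febuxostat is cleared with a ~6 h half-life.
#'
#' @param drug `"lesinurad"`, `"oxypurinol"` or `"febuxostat"`.
#' @return a [pk_params()].
#' @export
ua_pk_defaults <- function(drug = c("lesinurad", "oxypurinol", "febuxostat")) {
  drug <- match.arg(drug)
  switch(drug,
    lesinurad  = pk_params(ka = 1, cl_f = 4.2, v_f = 30),
    oxypurinol = pk_params(ka = 1, cl_f = 1.25, v_f = 36),
    febuxostat = pk_params(ka = 2, cl_f = 6, v_f = 50))
}

#' Virtual population specification
#'
#' Distributions from which virtual subjects' baseline physiology is
#' drawn: GFR uniform over a range, baseline fractional excretion
#' log-normal, baseline serum uric acid normal (truncated above the
#' solubility limit 6.8 mg/dL for hyperuricemic cohorts, below it
#' otherwise). Defaults emulate healthy Phase-I subjects (fractional
#' excretion around 0.07, the normal 7-12 percent range) or
#' hyperuricemic underexcreters (median 0.04) when `hyperuricemic` is
#' set. All sampled subjects satisfy the physiology invariants; the
#' sampler rejects and redraws violations.
#'
#' @param n number of subjects.
#' @param gfr_range_ml_min GFR range, mL/min.
#' @param fe0_median,fe0_gsd median and geometric SD of baseline
#'   fractional excretion.
#' @param s_ua_mean_mg_dl,s_ua_sd_mg_dl mean and SD of baseline serum
#'   uric acid, mg/dL.
#' @param hyperuricemic logical cohort flag.
#' @param v_ua,cl_i distribution volume (L) and intestinal clearance
#'   (L/h) assigned to every subject.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n,
                            gfr_range_ml_min = c(80, 120),
                            fe0_median = if (hyperuricemic) 0.04 else 0.07,
                            fe0_gsd = 1.4,
                            s_ua_mean_mg_dl = if (hyperuricemic) 9 else 5.5,
                            s_ua_sd_mg_dl = 1,
                            hyperuricemic = FALSE,
                            v_ua = 19, cl_i = 0.27) {
  stopifnot(n >= 1, length(gfr_range_ml_min) == 2L,
            all(gfr_range_ml_min > 0),
            gfr_range_ml_min[1] <= gfr_range_ml_min[2])
  if (fe0_median <= 0 || fe0_median >= 1) {
    stop("fe0_median must lie in (0, 1)")
  }
  structure(list(n = n, gfr_range_ml_min = gfr_range_ml_min,
                 fe0_median = fe0_median, fe0_gsd = fe0_gsd,
                 s_ua_mean_mg_dl = s_ua_mean_mg_dl,
                 s_ua_sd_mg_dl = s_ua_sd_mg_dl,
                 hyperuricemic = isTRUE(hyperuricemic),
                 v_ua = v_ua, cl_i = cl_i),
            class = "population_spec")
}

#' Sample a virtual population
#'
#' Draws `spec$n` subjects from a [population_spec()]. Each subject's
#' baseline production rate is back-calculated from their baseline serum
#' concentration, so every subject sits exactly at their drug-free
#' steady state. Deterministic given the seed.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed.
#' @return list of [physiology_state()] objects, with the hyperuricemia
#'   flag attached as attribute `hyperuricemic`.
#' @export
sample_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  draw_one <- function() {
    for (i in 1:100) {
      gfr <- stats::runif(1, spec$gfr_range_ml_min[1],
                          spec$gfr_range_ml_min[2])
      fe0 <- exp(stats::rnorm(1, log(spec$fe0_median), log(spec$fe0_gsd)))
      sua <- stats::rnorm(1, spec$s_ua_mean_mg_dl, spec$s_ua_sd_mg_dl)
      ok <- fe0 > 0 && fe0 < 1 && sua > 0 &&
        (if (spec$hyperuricemic) sua > 6.8 else sua <= 6.8)
      if (ok) {
        return(physiology_state(gfr, fe0, sua, v_ua = spec$v_ua,
                                cl_i = spec$cl_i))
      }
    }
    stop("population spec appears infeasible: 100 rejected draws in a row")
  }
  pop <- lapply(seq_len(spec$n), function(i) draw_one())
  attr(pop, "hyperuricemic") <- spec$hyperuricemic
  pop
}

#' Phase-I-style trial design
#'
#' Default multi-group design emulating the estimation dataset: single
#' oral doses of lesinurad alone over a dose range, and lesinurad
#' combined with allopurinol (modelled through its active metabolite
#' oxypurinol) or febuxostat. Serum uric acid is sampled serially over
#' 24 h and urine is collected in four 6-h intervals.
#'
#' @param groups data frame with columns `id`, `lesinurad_mg` (0 for
#'   none), `xoi` (`NA`, `"oxypurinol"` or `"febuxostat"`), `xoi_mg`,
#'   `days` (number of once-daily doses; observations are collected
#'   over the 24 h after the last dose) and `hyperuricemic`. The
#'   default emulates the estimation dataset: single doses of
#'   lesinurad alone spanning 50-1600 mg, and one week of once-daily
#'   combination dosing with allopurinol (100-900 mg,
#'   oxypurinol-equivalents) or febuxostat (40/80 mg), sampled on day 7
#'   when oxypurinol has accumulated to its daily average near
#'   10,000 ng/mL at 300 mg.
#' @param serum_times serum sampling times, h after the last dose.
#' @param urine_intervals two-column matrix of (start, end) h after the
#'   last dose.
#' @param n_subj subjects per group. Each subject contributes the full
#'   sampling schedule with independent residual error around the group
#'   mean, emulating fitting a mean model to all individual samples of
#'   a trial programme of about 270 subjects (15 per group).
#' @param error named list of [error_model()]s for `serum` (mg/L) and
#'   `urine` (mg).
#' @return object of class `trial_design`.
#' @export
phase1_design <- function(
    groups = data.frame(
      id = c(paste0("LSN", c(50, 100, 200, 400, 600, 800, 1200, 1600)),
             paste0("LSN", c(200, 400, 600), "QD7"),
             "LSN400+ALLO100", "LSN400+ALLO300", "LSN200+ALLO300",
             "LSN400+ALLO600", "LSN400+ALLO900",
             "LSN400+FBX40", "LSN400+FBX80"),
      lesinurad_mg = c(50, 100, 200, 400, 600, 800, 1200, 1600,
                       200, 400, 600,
                       400, 400, 200, 400, 400, 400, 400),
      xoi = c(rep(NA, 11), rep("oxypurinol", 5), rep("febuxostat", 2)),
      xoi_mg = c(rep(NA, 11), 100, 300, 300, 600, 900, 40, 80),
      days = c(rep(1L, 8), rep(7L, 10)),
      hyperuricemic = FALSE),
    serum_times = c(0.5, 1, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24),
    urine_intervals = cbind(c(0, 6, 12, 18), c(6, 12, 18, 24)),
    n_subj = 15L,
    error = ua_error_defaults()) {
  if (!"days" %in% names(groups)) groups$days <- 1L
  stopifnot(is.data.frame(groups),
            all(c("id", "lesinurad_mg", "xoi", "xoi_mg", "days",
                  "hyperuricemic") %in% names(groups)),
            all(groups$days >= 1L),
            inherits(error$serum, "error_model"),
            inherits(error$urine, "error_model"))
  window <- max(serum_times, urine_intervals)
  if (any(serum_times < 0) || any(serum_times > window)) {
    stop("serum sampling times must lie within the observation window")
  }
  stopifnot(n_subj >= 1L)
  structure(list(groups = groups, serum_times = sort(unique(serum_times)),
                 urine_intervals = urine_intervals, n_subj = as.integer(n_subj),
                 error = error, window = window),
            class = "trial_design")
}

# exposure attachments for one design row, using stand-in PK profiles
design_exposures <- function(row) {
  pin <- rin <- NULL
  dose_times <- (seq_len(row$days) - 1L) * 24
  if (!is.na(row$xoi)) {
    prof <- pk_profile(ua_pk_defaults(row$xoi),
                       data.frame(amount = rep(row$xoi_mg, row$days),
                                  time = dose_times))
    pin <- list(profile = prof,
                r_max_name = paste0("r_max_", row$xoi),
                p50_name = paste0("p50_", row$xoi,
                                  if (isTRUE(row$hyperuricemic) &&
                                      row$xoi == "febuxostat") "_hyper" else ""))
  }
  if (row$lesinurad_mg > 0) {
    prof <- pk_profile(ua_pk_defaults("lesinurad"),
                       data.frame(amount = rep(row$lesinurad_mg, row$days),
                                  time = dose_times))
    rin <- list(profile = prof,
                f_max_name = "f_max_lesinurad",
                p50_name = paste0("p50_lesinurad",
                                  if (isTRUE(row$hyperuricemic)) "_hyper"
                                  else ""))
  }
  list(pin = pin, rin = rin)
}

#' Generate a synthetic multi-group Phase-I-style trial
#'
#' Simulates every treatment group of the design from the uric acid
#' model at the supplied generating truth, then perturbs the noise-free
#' predictions with the combined additive-proportional error of each
#' observation stream (independent draws per observation, negative
#' values truncated at zero). One virtual subject from the population
#' provides each group's mean baseline physiology.
#'
#' @param population a [sample_population()] result with at least as
#'   many subjects as design groups.
#' @param design a [phase1_design()].
#' @param truth named parameter vector; defaults to
#'   [ua_param_defaults()].
#' @param seed integer seed for the noise streams (separate streams for
#'   serum and urine noise).
#' @return list with
#'   \describe{
#'     \item{groups}{list of [treatment_group()] objects ready for
#'       [fit_ua_model()].}
#'     \item{data}{tidy long-format data frame of all observations.}
#'     \item{truth}{the generating parameter vector.}
#'   }
#' @export
generate_trial <- function(population, design, truth = ua_param_defaults(),
                           seed = 1L) {
  stopifnot(inherits(design, "trial_design"),
            length(population) >= nrow(design$groups))
  n_g <- nrow(design$groups)
  em_s <- if (truth[["a_serum"]] == 0 && truth[["b_serum"]] == 0) NULL else
    error_model(truth[["a_serum"]], truth[["b_serum"]])
  em_u <- if (truth[["a_urine"]] == 0 && truth[["b_urine"]] == 0) NULL else
    error_model(truth[["a_urine"]], truth[["b_urine"]])
  # pre-drawn noise, one stream per observation type
  n_subj <- design$n_subj
  n_s <- length(design$serum_times) * n_subj
  n_u <- nrow(design$urine_intervals) * n_subj
  set.seed(seed)
  eps_serum <- matrix(stats::rnorm(n_g * n_s), nrow = n_g)
  set.seed(seed + 1L)
  eps_urine <- matrix(stats::rnorm(n_g * n_u), nrow = n_g)
  groups <- vector("list", n_g)
  rows <- list()
  for (k in seq_len(n_g)) {
    row <- design$groups[k, ]
    phys <- population[[k]]
    expo <- design_exposures(row)
    # noise-free model output at the generating truth
    kp0 <- baseline_production_rate(
      phys$s_ua_base, phys$gfr * phys$fe0 * phys$s_ua_base, truth[["cl_i"]])
    phys_truth <- structure(
      list(gfr = phys$gfr, fe0 = phys$fe0, kp0 = kp0,
           v_ua = truth[["v_ua"]], cl_i = truth[["cl_i"]],
           s_ua_base = phys$s_ua_base),
      class = "physiology_state")
    pin <- if (!is.null(expo$pin)) {
      list(profile = expo$pin$profile,
           params = production_inhibitor(truth[[expo$pin$r_max_name]],
                                         truth[[expo$pin$p50_name]]))
    }
    rin <- if (!is.null(expo$rin)) {
      list(profile = expo$rin$profile,
           params = reabsorption_inhibitor(truth[[expo$rin$f_max_name]],
                                           truth[[expo$rin$p50_name]]))
    }
    offset <- (row$days - 1L) * 24
    serum_times <- offset + design$serum_times
    urine_intervals <- offset + design$urine_intervals
    plan <- simulation_plan(phys_truth, pin = pin, rin = rin,
                            serum_times = serum_times,
                            urine_intervals = urine_intervals,
                            horizon = offset + design$window)
    res <- run_simulation(plan, n_grid = 2L)
    f_s <- rep(res$serum_obs$conc, times = n_subj)
    f_u <- rep(res$urine$amount, times = n_subj)
    t_s <- rep(serum_times, times = n_subj)
    u_start <- rep(res$urine$start, times = n_subj)
    u_end <- rep(res$urine$end, times = n_subj)
    subj_s <- rep(seq_len(n_subj), each = length(serum_times))
    subj_u <- rep(seq_len(n_subj), each = nrow(res$urine))
    y_s <- if (is.null(em_s)) f_s else
      pmax(f_s + error_sd(em_s, f_s) * eps_serum[k, ], 0)
    y_u <- if (is.null(em_u)) f_u else
      pmax(f_u + error_sd(em_u, f_u) * eps_urine[k, ], 0)
    groups[[k]] <- treatment_group(
      id = row$id,
      gfr_ml_min = convert_units(phys$gfr, "L/h", "mL/min"),
      fe0 = phys$fe0,
      base_s_ua_mg_dl = convert_units(phys$s_ua_base, "mg/L", "mg/dL"),
      serum = data.frame(time = t_s, value = y_s),
      urine = data.frame(start = u_start, end = u_end, value = y_u),
      pin = expo$pin, rin = expo$rin,
      hyperuricemic = isTRUE(row$hyperuricemic))
    rows[[length(rows) + 1L]] <- data.frame(
      group = row$id, subject = subj_s, time_h = t_s, record = "serum_ua",
      value = y_s, units = "mg/L",
      interval_start = NA_real_, interval_end = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      group = row$id, subject = subj_u, time_h = (u_start + u_end) / 2,
      record = "urine_ua", value = y_u, units = "mg",
      interval_start = u_start, interval_end = u_end)
  }
  list(groups = groups, data = do.call(rbind, rows), truth = truth)
}

#' Generate a synthetic Phase-III-style hyperuricemic cohort
#'
#' Assigns each hyperuricemic subject a steady daily-average uricosuric
#' exposure (log-normal across subjects), computes the true on-treatment
#' fractional excretion through the Emax model and the true on-treatment
#' serum uric acid through the steady state; for subjects on background
#' allopurinol the on-treatment concentration is inflated by the
#' lesinurad-oxypurinol interaction factor. The observed on-treatment
#' serum uric acid is the mean of `n_visits` monthly values perturbed
#' with the serum residual error.
#'
#' @param population hyperuricemic [sample_population()] result.
#' @param rin_params [reabsorption_inhibitor()] (hyperuricemic
#'   half-maximal concentration).
#' @param n_visits number of monthly on-treatment visits averaged.
#' @param seed integer seed.
#' @param conc_median,conc_gsd log-normal daily-average exposure
#'   distribution, ng/mL (default median 2000, the daily average of a
#'   200 mg lesinurad dose under the stand-in PK model).
#' @param allopurinol_fraction fraction of subjects flagged as receiving
#'   background allopurinol.
#' @param error serum [error_model()] (mg/L scale); `NULL` for
#'   noise-free.
#' @param oxy_params,oxy_conc,reduction interaction-correction inputs,
#'   as in [predict_phase3_change()].
#' @return list of [phase3_subject()] records; the generating truth per
#'   subject (`fe_on`, exposure, true change) is attached as attribute
#'   `truth` (data frame).
#' @export
generate_phase3_cohort <- function(population, rin_params,
                                   n_visits = 6L, seed = 1L,
                                   conc_median = 2000, conc_gsd = 1.5,
                                   allopurinol_fraction = 0.5,
                                   error = ua_error_defaults()$serum,
                                   oxy_params = ua_drug_params("oxypurinol"),
                                   oxy_conc = 10000, reduction = 0.32) {
  stopifnot(inherits(rin_params, "reabsorption_inhibitor"))
  if (!isTRUE(attr(population, "hyperuricemic"))) {
    stop("generate_phase3_cohort requires a hyperuricemic population")
  }
  n <- length(population)
  set.seed(seed)
  concs <- exp(stats::rnorm(n, log(conc_median), log(conc_gsd)))
  allo <- stats::runif(n) < allopurinol_fraction
  set.seed(seed + 1L)
  eps <- matrix(stats::rnorm(n * n_visits), nrow = n)
  subjects <- vector("list", n)
  truth <- data.frame(id = seq_len(n), conc = concs, allopurinol = allo,
                      fe_on = NA_real_, true_change = NA_real_)
  for (i in seq_len(n)) {
    phys <- population[[i]]
    fe_on <- fe_under_drug(phys$fe0, rin_params, concs[i])
    conc_on <- phys$kp0 / (phys$cl_i + phys$gfr * fe_on)
    if (allo[i]) {
      conc_on <- conc_on *
        oxypurinol_interaction_factor(oxy_conc, oxy_params, reduction)
    }
    visits <- if (is.null(error)) rep(conc_on, n_visits) else
      pmax(conc_on + error_sd(error, conc_on) * eps[i, ], 0)
    subjects[[i]] <- phase3_subject(
      id = i,
      base_s_ua_mg_dl = convert_units(phys$s_ua_base, "mg/L", "mg/dL"),
      gfr_ml_min = convert_units(phys$gfr, "L/h", "mL/min"),
      fe0 = phys$fe0, fe_on = fe_on,
      s_ua_on_mg_dl = convert_units(mean(visits), "mg/L", "mg/dL"),
      allopurinol = allo[i])
    truth$fe_on[i] <- fe_on
    truth$true_change[i] <- conc_on / phys$s_ua_base - 1
  }
  attr(subjects, "truth") <- truth
  subjects
}
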