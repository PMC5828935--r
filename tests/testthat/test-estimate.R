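test_that("the combined-error likelihood matches direct density evaluation", {
  truth <- tiny_noise_truth()
  design <- small_design()
  pop <- sample_population(population_spec(3), seed = 11)
  trial <- generate_trial(pop, design, truth = truth, seed = 11)
  spec <- fit_spec(free = c(cl_i = 0.27, v_ua = 19),
                   fixed = truth[setdiff(names(truth),
                                         c("cl_i", "v_ua"))])
  # oracle: rebuild every prediction by simulation and sum dnorm densities
  oracle <- 0
  for (g in trial$groups) {
    phys <- physiology_state(convert_units(g$gfr, "L/h", "mL/min"),
                             g$fe0,
                             convert_units(g$base_conc, "mg/L", "mg/dL"),
                             v_ua = 19, cl_i = 0.27)
    plan <- simulation_plan(
      phys, rin = list(profile = g$rin$profile,
                       params = ua_drug_params("lesinurad")),
      serum_times = unique(g$serum$time),
      urine_intervals = unique(cbind(g$urine$start, g$urine$end)),
      horizon = 24)
    res <- run_simulation(plan, method = "exponential", h_exp = 0.05)
    f_s <- res$serum_obs$conc[match(g$serum$time, res$serum_obs$time)]
    sd_s <- sqrt(truth["a_serum"]^2 + (truth["b_serum"] * f_s)^2)
    oracle <- oracle - sum(stats::dnorm(g$serum$value, f_s, sd_s,
                                        log = TRUE))
    f_u <- res$urine$amount[match(g$urine$start, res$urine$start)]
    sd_u <- sqrt(truth["a_urine"]^2 + (truth["b_urine"] * f_u)^2)
    oracle <- oracle - sum(stats::dnorm(g$urine$value, f_u, sd_u,
                                        log = TRUE))
  }
  nll <- neg_log_likelihood(c(cl_i = 0.27, v_ua = 19), trial$groups, spec)
  expect_equal(nll, oracle, tolerance = 1e-12)
  # permuting observation order leaves the objective unchanged
  shuffled <- lapply(trial$groups, function(g) {
    g$serum <- g$serum[rev(seq_len(nrow(g$serum))), ]
    g$urine <- g$urine[rev(seq_len(nrow(g$urine))), ]
    g
  })
  expect_equal(neg_log_likelihood(c(cl_i = 0.27, v_ua = 19),
                                  shuffled, spec), nll, tolerance = 1e-12)
})

test_that("with b = 0 the likelihood reduces to the additive-Gaussian form", {
  em <- error_model(a = 2, b = 0)
  y <- c(5, 6, 7); f <- c(5.5, 6, 6.2)
  wr <- weighted_residuals(y, f, em)
  expect_equal(wr$wres, (y - f) / 2)
  # single exact observation: NLL = 0.5 log(2 pi) + log(sd)
  expect_equal(-stats::dnorm(6, 6, 2, log = TRUE),
               0.5 * log(2 * pi) + log(2))
})

test_that("weighted residuals match hand arithmetic and are standardised", {
  wr <- weighted_residuals(6.45, 6.0, error_model(0.45, 0.15))
  expect_equal(wr$wres, 0.45 / sqrt(0.45^2 + 0.9^2), tolerance = 1e-9)
  expect_equal(wr$wres, 0.447, tolerance = 1e-3)
  expect_equal(weighted_residuals(5, 5, error_model(1, 0.1))$wres, 0)
  # residuals of correctly specified synthetic data: mean ~ 0, SD ~ 1
  truth <- ua_param_defaults()
  design <- small_design(n_subj = 150L)
  pop <- sample_population(population_spec(3), seed = 5)
  trial <- generate_trial(pop, design, truth = truth, seed = 5)
  em_s <- error_model(truth[["a_serum"]], truth[["b_serum"]])
  g <- trial$groups[[2]]
  phys <- physiology_state(convert_units(g$gfr, "L/h", "mL/min"), g$fe0,
                           convert_units(g$base_conc, "mg/L", "mg/dL"))
  res <- run_simulation(simulation_plan(
    phys, rin = list(profile = g$rin$profile,
                     params = ua_drug_params("lesinurad")),
    serum_times = unique(g$serum$time), horizon = 24))
  f <- res$serum_obs$conc[match(g$serum$time, res$serum_obs$time)]
  wres <- weighted_residuals(g$serum$value, f, em_s)$wres
  expect_equal(mean(wres), 0, tolerance = 0.1)
  expect_equal(stats::sd(wres), 1, tolerance = 0.1)
})

test_that("near-noise-free data are recovered to optimiser tolerance", {
  truth <- tiny_noise_truth()
  design <- small_design()
  pop <- sample_population(population_spec(3), seed = 3)
  trial <- generate_trial(pop, design, truth = truth, seed = 3)
  free <- c(cl_i = 0.4, v_ua = 14)
  spec <- fit_spec(free, fixed = truth[setdiff(names(truth), names(free))])
  fit <- fit_ua_model(trial$groups, spec, control = list(reltol = 1e-11))
  expect_true(fit$convergence)
  expect_equal(unname(fit$estimates["cl_i"]), 0.27, tolerance = 0.01)
  expect_equal(unname(fit$estimates["v_ua"]), 19, tolerance = 0.01)
  expect_true(all(is.finite(fit$se)))
  expect_true(all(c("estimate") %in% "estimate"))
})

test_that("a one-parameter fit agrees with a grid-search oracle", {
  truth <- ua_param_defaults()
  design <- small_design(n_subj = 3L)
  pop <- sample_population(population_spec(3), seed = 9)
  trial <- generate_trial(pop, design, truth = truth, seed = 9)
  free <- c(v_ua = 15)
  spec <- fit_spec(free, fixed = truth[setdiff(names(truth), names(free))])
  fit <- fit_ua_model(trial$groups, spec)
  grid <- seq(14, 26, by = 0.05)
  nlls <- vapply(grid, function(v)
    neg_log_likelihood(c(v_ua = v), trial$groups, spec), numeric(1))
  expect_equal(unname(fit$estimates["v_ua"]), grid[which.min(nlls)],
               tolerance = 0.01)
  expect_lte(fit$objective, min(nlls) + 1e-6)
  # local convexity of the profile around the optimum
  vhat <- unname(fit$estimates["v_ua"])
  for (eps in c(0.95, 1.05)) {
    expect_gt(neg_log_likelihood(c(v_ua = vhat * eps), trial$groups, spec),
              fit$objective)
  }
})

test_that("adequacy report flags imprecise parameters and residual trends", {
  mk_fit <- function(rse, wres, time = seq_along(wres)) {
    structure(list(
      estimates = c(cl_i = 0.27), se = c(cl_i = 0.27 * rse / 100),
      rse_pct = c(cl_i = rse), objective = 0, convergence = TRUE,
      residuals = data.frame(observed = wres, predicted = seq_along(wres),
                             wres = wres, stream = "serum", time = time,
                             group = "g"),
      spec = NULL, n_obs = length(wres)), class = "ua_fit")
  }
  set.seed(1)
  flat <- rnorm(200)
  expect_true(adequacy_report(mk_fit(12, flat))$pass)
  expect_equal(adequacy_report(mk_fit(45, flat))$rse_flags, "cl_i")
  # systematic drift in the residuals versus time must be flagged
  drift <- flat + seq(-1.5, 1.5, length.out = 200)
  rep_drift <- adequacy_report(mk_fit(12, drift))
  expect_true("time" %in% rep_drift$trend_flags ||
                "prediction" %in% rep_drift$trend_flags)
  expect_false(rep_drift$pass)
})

test_that("fit specifications are validated", {
  expect_error(fit_spec(c(0.3), fixed = c(v_ua = 19)), "named")
  expect_error(fit_spec(c(cl_i = 0.3), fixed = c(cl_i = 0.27, v_ua = 19,
                                                 a_serum = 4.5,
                                                 b_serum = 0.15,
                                                 a_urine = 50,
                                                 b_urine = 0.29)),
               "both free and fixed")
  expect_error(fit_spec(c(cl_i = 0.3, v_ua = 19)), "a_serum")
  expect_error(error_model(0, 0), "non-zero")
  expect_error(error_model(-1, 0.1), "non-negative")
})
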