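test_that("production inhibition reproduces the oxypurinol benchmark", {
  oxy <- ua_drug_params("oxypurinol")
  # 10,000 ng/mL oxypurinol: 0.84 x 10/24 = 35% decrease in production,
  # and by steady-state linearity a 35% serum uric acid decrease
  expect_equal(production_rate_under_drug(45.36, oxy, 10000),
               0.65 * 45.36)
  expect_equal(production_rate_under_drug(45.36, oxy, 0), 45.36)
  expect_equal(production_rate_under_drug(45.36, oxy, oxy$p50_pin),
               45.36 * (1 - 0.84 / 2))
  # monotone non-increasing in concentration, bounded by (1 - r_max)
  conc <- c(0, 10^seq(0, 6, by = 0.5))
  kp <- production_rate_under_drug(1, oxy, conc)
  expect_true(all(diff(kp) < 0))
  expect_true(all(kp >= 1 - oxy$r_max & kp <= 1))
  # multiplicative in kp0
  expect_equal(production_rate_under_drug(7, oxy, 5000),
               7 * production_rate_under_drug(1, oxy, 5000))
})

test_that("fractional excretion effect is additive, saturable and bounded", {
  les <- ua_drug_params("lesinurad")
  expect_equal(fe_under_drug(0.07, les, 1e15), 0.63, tolerance = 1e-9)
  expect_equal(fe_under_drug(0.07, les, 0), 0.07)
  expect_equal(fe_under_drug(0.07, les, les$p50_rin), 0.07 + 0.28)
  # the increment is independent of the starting coefficient
  conc <- 10^seq(2, 5, by = 0.5)
  expect_equal(fe_under_drug(0.03, les, conc) - 0.03,
               fe_under_drug(0.12, les, conc) - 0.12)
  expect_true(all(diff(fe_under_drug(0.07, les, conc)) > 0))
  expect_error(fe_under_drug(0.5, les, 100), "exceeds 1")
})

test_that("drug parameter defaults carry the hyperuricemic switch", {
  expect_equal(ua_drug_params("oxypurinol")$r_max, 0.84)
  expect_equal(ua_drug_params("oxypurinol")$p50_pin, 14000)
  expect_equal(ua_drug_params("febuxostat")$p50_pin, 87)
  expect_equal(ua_drug_params("febuxostat", TRUE)$p50_pin, 120)
  expect_equal(ua_drug_params("lesinurad")$p50_rin, 11000)
  expect_equal(ua_drug_params("lesinurad", TRUE)$p50_rin, 23000)
  expect_equal(ua_drug_params("lesinurad")$f_max, 0.56)
})

test_that("oxypurinol interaction factor and corrected change match hand algebra", {
  oxy <- ua_drug_params("oxypurinol")
  # (1 - 0.84 x 6800/20800) / (1 - 0.84 x 10000/24000)
  expect_equal(oxypurinol_interaction_factor(10000, oxy, 0.32),
               (1 - 0.84 * 6800 / 20800) / 0.65, tolerance = 1e-9)
  expect_equal(oxypurinol_interaction_factor(10000, oxy, 0.32),
               1.11598, tolerance = 1e-5)
  expect_equal(oxypurinol_interaction_factor(10000, oxy, 0), 1)
  inert <- production_inhibitor(0, 14000)
  expect_equal(oxypurinol_interaction_factor(10000, inert, 0.32), 1)
  expect_equal(corrected_relative_change(-0.5, 1.11598), -0.44201)
  expect_equal(corrected_relative_change(-0.3, 1), -0.3)
  expect_equal(corrected_relative_change(0, 1.1), 0.1, tolerance = 1e-12)
})

test_that("simulated oral concentration profiles behave like Bateman curves", {
  pk <- ua_pk_defaults("lesinurad")
  prof <- pk_profile(pk, data.frame(amount = 200, time = 0))
  expect_equal(conc_at(prof, 0), 0)
  expect_true(all(conc_at(prof, c(1, 5, 23)) > 0))
  # superposition: two doses equal the sum of the single-dose responses
  prof2 <- pk_profile(pk, data.frame(amount = c(200, 200), time = c(0, 12)))
  shifted <- pk_profile(pk, data.frame(amount = 200, time = 12))
  tt <- seq(0, 36, by = 0.5)
  expect_equal(conc_at(prof2, tt),
               conc_at(prof, tt) + conc_at(shifted, tt), tolerance = 1e-12)
  # AUC(0, Inf) equals dose / CL in mg/L x h (the profile is in ng/mL)
  auc <- stats::integrate(function(t) conc_at(prof, t) / 1000,
                          0, Inf, rel.tol = 1e-9)$value
  expect_equal(auc, 200 / pk$cl_f, tolerance = 1e-6)
  # flip-flop degeneracy: the analytic limit form stays finite/continuous
  pk_eq <- pk_params(ka = 0.14, cl_f = 4.2, v_f = 30)  # ka == ke
  prof_eq <- pk_profile(pk_eq, data.frame(amount = 200, time = 0))
  near <- pk_profile(pk_params(0.1400001, 4.2, 30),
                     data.frame(amount = 200, time = 0))
  expect_equal(conc_at(prof_eq, c(1, 5, 20)), conc_at(near, c(1, 5, 20)),
               tolerance = 1e-4)
  expect_error(pk_profile(pk, data.frame(amount = -1, time = 0)), "positive")
})

test_that("spline interpolation honours observations and never goes negative", {
  times <- c(0, 1, 2, 4, 8, 12, 24)
  concs <- c(0, 4000, 9000, 7000, 3000, 1200, 100)
  prof <- interpolate_observed_concentrations(times, concs)
  expect_equal(conc_at(prof, times), concs)
  expect_error(conc_at(prof, 25), "support")
  zero <- interpolate_observed_concentrations(times, rep(0, 7))
  expect_equal(conc_at(zero, seq(0, 24, by = 0.1)), rep(0, 241))
  expect_error(interpolate_observed_concentrations(c(0, 0, 1), c(1, 2, 3)),
               "duplicate")
  # random monotone-decay fixtures: clipping keeps the profile non-negative
  set.seed(42)
  for (i in 1:20) {
    tt <- sort(runif(6, 0, 24))
    cc <- sort(runif(6, 0, 10000), decreasing = TRUE)
    p <- interpolate_observed_concentrations(tt, cc)
    expect_true(all(conc_at(p, seq(min(tt), max(tt), length.out = 200)) >= 0))
  }
})
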