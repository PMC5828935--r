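test_that("a drug-free simulation stays at baseline", {
  phys <- healthy_phys()
  res <- run_simulation(simulation_plan(phys))
  ss <- steady_state(phys)
  expect_equal(res$serum$conc, rep(ss$conc, nrow(res$serum)),
               tolerance = 1e-9)
  expect_equal(res$urine$amount, rep(ss$x_ua * 6, 4), tolerance = 1e-8)
  expect_equal(unname(relative_change_24h(res)), c(0, 0, 0),
               tolerance = 1e-8)
})

test_that("constant uricosuric exposure decays serum to the shifted steady state", {
  phys <- healthy_phys()
  les <- ua_drug_params("lesinurad")
  conc <- 8000
  rin <- list(profile = constant_profile(conc), params = les)
  plan <- simulation_plan(phys, rin = rin, serum_times = c(0, 400),
                          urine_intervals = cbind(0, 400), horizon = 400)
  res <- run_simulation(plan)
  fe_new <- fe_under_drug(phys$fe0, les, conc)
  target <- steady_state(phys, fe = fe_new)$conc
  # long-time ODE value agrees with the closed-form steady state
  expect_equal(res$serum_obs$conc[2], target, tolerance = 1e-6)
  # monotone approach from above
  dense <- run_simulation(simulation_plan(phys, rin = rin, horizon = 48,
                                          serum_times = seq(0, 48, 2),
                                          urine_intervals = cbind(0, 48)))
  expect_true(all(diff(dense$serum$conc) <= 1e-10))
})

test_that("the serum trajectory is linear in the production rate", {
  phys <- healthy_phys()
  les <- lesinurad_exposure(400)
  r1 <- run_simulation(simulation_plan(phys, rin = les))
  phys2 <- physiology_state(100, phys$fe0, 12, kp0 = 2 * phys$kp0,
                            cl_i = phys$cl_i)
  # doubling kp0 (and hence the baseline conc) doubles the whole profile
  r2 <- run_simulation(simulation_plan(phys2, rin = les))
  expect_equal(r2$serum$conc, 2 * r1$serum$conc, tolerance = 1e-7)
})

test_that("urine intervals integrate the renal excretion flux", {
  phys <- healthy_phys()
  res <- run_simulation(simulation_plan(phys, rin = lesinurad_exposure(600)),
                        n_grid = 961L)
  # contiguous interval amounts equal the integral of gfr x fe(t) x conc(t)
  flux <- phys$gfr * res$effects$fe * res$serum$conc
  total_quad <- sum(diff(res$serum$time) *
                      (head(flux, -1) + tail(flux, -1)) / 2)
  expect_equal(sum(res$urine$amount), total_quad, tolerance = 1e-4)
  expect_true(all(res$urine$amount >= 0))
})

test_that("production and reabsorption effects commute at steady state", {
  phys <- healthy_phys()
  oxy <- ua_drug_params("oxypurinol")
  les <- ua_drug_params("lesinurad")
  pin <- list(profile = constant_profile(10000), params = oxy)
  rin <- list(profile = constant_profile(8000), params = les)
  plan <- simulation_plan(phys, pin = pin, rin = rin,
                          serum_times = c(0, 600),
                          urine_intervals = cbind(0, 600), horizon = 600)
  res <- run_simulation(plan)
  kp_new <- production_rate_under_drug(phys$kp0, oxy, 10000)
  fe_new <- fe_under_drug(phys$fe0, les, 8000)
  expect_equal(res$serum_obs$conc[2],
               steady_state(phys, kp = kp_new, fe = fe_new)$conc,
               tolerance = 1e-6)
})

test_that("exponential propagator agrees with the adaptive solver", {
  phys <- healthy_phys()
  oxy <- list(profile = pk_profile(ua_pk_defaults("oxypurinol"),
                                   data.frame(amount = 300, time = 0)),
              params = ua_drug_params("oxypurinol"))
  plan <- simulation_plan(phys, pin = oxy, rin = lesinurad_exposure(400))
  a <- run_simulation(plan)
  b <- run_simulation(plan, method = "exponential", h_exp = 0.05)
  expect_equal(b$serum_obs$conc, a$serum_obs$conc, tolerance = 1e-4)
  expect_equal(b$urine$amount, a$urine$amount, tolerance = 1e-4)
})

test_that("24-h summaries carry the expected signs and dose ordering", {
  phys <- healthy_phys()
  lo <- relative_change_24h(run_simulation(
    simulation_plan(phys, rin = lesinurad_exposure(200))))
  hi <- relative_change_24h(run_simulation(
    simulation_plan(phys, rin = lesinurad_exposure(800))))
  # a uricosuric lowers serum and raises urinary excretion
  expect_lt(lo[["serum"]], 0)
  expect_gt(lo[["urine"]], 0)
  expect_gt(lo[["fe"]], 0)
  # magnitudes grow with dose
  expect_lt(hi[["serum"]], lo[["serum"]])
  expect_gt(hi[["urine"]], lo[["urine"]])
})

test_that("post-dose fractional excretion back-calculation is consistent", {
  expect_equal(fe_post_from_observations(3.6, 120, 311.04), 0.03)
  expect_equal(fe_post_from_observations(3.6, 120, 0), 0)
  expect_error(fe_post_from_observations(3.6, 0, 100), "positive")
  # steady-state round trip: simulated drug-free observations recover fe0
  phys <- healthy_phys()
  res <- run_simulation(simulation_plan(phys))
  ch <- relative_change_24h(res)
  expect_equal(ch[["fe"]], 0, tolerance = 1e-8)
})

test_that("simulation plans validate their inputs", {
  phys <- healthy_phys()
  expect_error(simulation_plan(phys, urine_intervals = cbind(0, 30)),
               "within")
  expect_error(simulation_plan(phys,
                               urine_intervals = cbind(c(0, 5), c(6, 12))),
               "non-overlapping")
  short <- list(profile = interpolate_observed_concentrations(
    c(0, 1, 2), c(0, 10, 5)), params = ua_drug_params("lesinurad"))
  expect_error(simulation_plan(phys, rin = short), "cover")
  tidy <- simulation_to_tidy(run_simulation(simulation_plan(phys)), id = "g1")
  expect_equal(nrow(tidy), length(simulation_plan(phys)$serum_times) + 4)
  expect_true(all(c("id", "time_h", "variable", "value", "units")
                  %in% names(tidy)))
})
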