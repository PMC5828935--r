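test_that("serum/urine derivatives reproduce hand-computed balances", {
  phys <- fig9_phys()  # kp0 45.36, cl_i 0.27, gfr 3.6 L/h, fe0 0.03, v 19
  # at the steady state amount (120 mg/L x 19 L) the serum balance is zero
  d <- ua_derivatives(s_ua = 2280, kp = 45.36, fe = 0.03, phys)
  expect_equal(unname(d["ds_ua"]), 0, tolerance = 1e-12)
  expect_equal(unname(d["du_ua"]), 12.96)
  # empty system
  d0 <- ua_derivatives(0, kp = 0, fe = 0.03, phys)
  expect_equal(unname(d0), c(0, 0))
  # no renal route: dU = 0, serum balance is production minus intestinal
  d1 <- ua_derivatives(s_ua = 50 * 19, kp = 10, fe = 0, phys)
  expect_equal(unname(d1["du_ua"]), 0)
  expect_equal(unname(d1["ds_ua"]), 10 - 0.27 * 50)
  expect_error(ua_derivatives(NaN, 1, 0.1, phys), "s_ua")
  expect_error(ua_derivatives(10, -1, 0.1, phys), "non-negative")
})

test_that("steady state matches hand algebra and rejects zero clearance", {
  phys <- fig9_phys()
  ss <- steady_state(phys)
  expect_equal(ss$conc, 120)
  expect_equal(ss$x_ua, 12.96)
  expect_equal(ss$cl_total, 0.27 + 3.6 * 0.03)
  expect_equal(steady_state(phys, kp = 0)$conc, 0)
  # mass balance invariant of the type: conc x cl_total = kp
  expect_equal(ss$conc * ss$cl_total, phys$kp0)
})

test_that("baseline back-calculations invert the steady state exactly", {
  expect_equal(baseline_production_rate(120, 12.96, 0.27), 45.36)
  expect_equal(baseline_production_rate(0, 0, 0), 0)
  expect_equal(baseline_fractional_excretion(120, 12.96, 3.6), 0.03)
  expect_equal(baseline_fractional_excretion(120, 0, 3.6), 0)
  expect_warning(baseline_fractional_excretion(10, 100, 1), "exceeds 1")
  expect_error(baseline_fractional_excretion(0, 1, 3.6), "positive")
  # round trip over a parameter grid: Eq-5/6-style forward then Eq-7/8-style
  # inverse recovers (kp, fe) to machine precision
  for (gfr in c(30, 60, 120)) {
    for (fe in c(0.01, 0.05, 0.2)) {
      for (kp in c(10, 45, 80)) {
        phys <- physiology_state(gfr, fe, 6, kp0 = kp)
        ss <- steady_state(phys, kp = kp, fe = fe)
        expect_equal(baseline_production_rate(ss$conc, ss$x_ua, phys$cl_i),
                     kp, tolerance = 1e-12)
        expect_equal(
          baseline_fractional_excretion(ss$conc, ss$x_ua, phys$gfr),
          fe, tolerance = 1e-12)
      }
    }
  }
})

test_that("steady-state concentration is monotone in clearances and linear in kp", {
  base <- list(gfr = 60, fe = 0.05, cl_i = 0.27, kp = 45)
  conc <- function(gfr, fe, cl_i, kp) {
    phys <- physiology_state(gfr, fe, 6, cl_i = cl_i, kp0 = kp)
    steady_state(phys, kp = kp, fe = fe)$conc
  }
  grid <- seq(0.5, 2, length.out = 7)
  for (par in c("gfr", "fe", "cl_i")) {
    vals <- sapply(grid, function(m) {
      a <- base; a[[par]] <- a[[par]] * m
      do.call(conc, a)
    })
    expect_true(all(diff(vals) < 0), info = par)
  }
  # linear in kp, hence percent reduction by a production inhibitor is
  # independent of GFR, FE and the baseline production rate
  vals <- sapply(grid, function(m) {
    a <- base; a$kp <- a$kp * m
    do.call(conc, a)
  })
  expect_equal(vals, grid * vals[2] / grid[2], tolerance = 1e-12)
  for (scale in c(0.25, 0.5, 0.8)) {
    p1 <- physiology_state(90, 0.08, 7)
    p2 <- physiology_state(40, 0.02, 9, cl_i = 0.35)
    for (p in list(p1, p2)) {
      expect_equal(steady_state(p, kp = scale * p$kp0)$conc,
                   scale * steady_state(p)$conc, tolerance = 1e-12)
    }
  }
})

test_that("unit conversions are exact and invertible", {
  expect_equal(convert_units(12, "mg/dL", "mg/L"), 120)
  expect_equal(convert_units(60, "mL/min", "L/h"), 3.6)
  expect_equal(convert_units(2, "mg/h", "mg/24h"), 48)
  for (pair in list(c("mg/dL", "mg/L"), c("mL/min", "L/h"),
                    c("mg/h", "mg/24h"))) {
    x <- c(0.3, 1, 57)
    expect_equal(convert_units(convert_units(x, pair[1], pair[2]),
                               pair[2], pair[1]), x)
  }
  expect_error(convert_units(1, "mg/dL", "L/h"), "unsupported")
})

test_that("Cockcroft-Gault follows the standard formulation", {
  expect_equal(cockcroft_gault(40, 72, 1.0, "male"), 100)
  expect_equal(cockcroft_gault(40, 72, 1.0, "female"), 85)
  expect_equal(cockcroft_gault(40, 0, 1.0, "male"), 0)
  expect_error(cockcroft_gault(150, 72, 1.0, "male"), "140")
  expect_error(cockcroft_gault(40, 72, 0, "male"), "creatinine")
})

test_that("mass is conserved over a drug-free response transient", {
  # hold production inhibited at a constant level so the system relaxes
  # from the drug-free steady state; production input must equal the
  # change in serum amount plus intestinal and urinary losses
  phys <- healthy_phys()
  pin <- list(profile = constant_profile(10000),
              params = production_inhibitor(0.5, 10000))
  plan <- simulation_plan(phys, pin = pin,
                          serum_times = c(0, 24), horizon = 24)
  res <- run_simulation(plan)
  kp_const <- production_rate_under_drug(phys$kp0, pin$params, 10000)
  dS <- (res$serum_obs$conc[2] - res$serum_obs$conc[1]) * phys$v_ua
  dU <- sum(res$urine$amount)
  intestinal <- dU * phys$cl_i / (phys$gfr * phys$fe0)
  expect_equal(kp_const * 24, dS + dU + intestinal, tolerance = 1e-6)
})
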