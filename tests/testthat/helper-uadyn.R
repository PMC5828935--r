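# Shared fixtures for the test suite.

# the worked nomogram scenario: 12 mg/dL baseline, GFR 60 mL/min, FE,0 0.03
fig9_phys <- function() physiology_state(60, 0.03, 12)

# a healthy-volunteer physiology used in simulation tests
healthy_phys <- function() physiology_state(100, 0.07, 6)

# single-dose lesinurad exposure at a given dose (mg)
lesinurad_exposure <- function(dose_mg = 400) {
  list(profile = pk_profile(ua_pk_defaults("lesinurad"),
                            data.frame(amount = dose_mg, time = 0)),
       params = ua_drug_params("lesinurad"))
}

# small lesinurad-only design for fast estimation tests
small_design <- function(n_subj = 1L) {
  phase1_design(groups = data.frame(
    id = paste0("LSN", c(100, 400, 1600)),
    lesinurad_mg = c(100, 400, 1600),
    xoi = NA_character_, xoi_mg = NA_real_,
    days = 1L, hyperuricemic = FALSE),
    serum_times = c(1, 2, 4, 8, 12, 16, 24),
    n_subj = n_subj)
}

# near-noise-free generating truth (tiny additive SD keeps the
# likelihood defined)
tiny_noise_truth <- function() {
  truth <- ua_param_defaults()
  truth[c("a_serum", "b_serum", "a_urine", "b_urine")] <-
    c(0.001, 0, 0.01, 0)
  truth
}
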