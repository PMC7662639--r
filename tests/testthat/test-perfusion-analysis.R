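geom <- segment_geometry("jejunum")

make_series <- function(marker_conc, drug_conc = NULL,
                        times = seq(0, 10 * (length(marker_conc) - 1), by = 10),
                        v_nom = 20, s = 0.4, cprime = 56, c0 = 100) {
  if (is.null(drug_conc)) drug_conc <- rep(c0, length(marker_conc) - 1)
  perfusion_series(times, marker_conc, drug_conc, cprime, v_nom, c0, s, geom)
}

test_that("initial volume inverts the marker dilution", {
  expect_equal(initial_volume(make_series(c(56, 58, 60, 62))), 20)
  expect_equal(initial_volume(make_series(c(58.8, 60, 61, 62))),
               56 * 20 / 58.8) # 19.0476 mL
})

test_that("volume trace matches the step-by-step marker-amount ledger", {
  cp <- c(56, 58.8, 61.6, 63.1)
  s <- make_series(cp)
  tr <- volume_trace(s, "recursive")
  oracle <- ledger_volume_oracle(initial_volume(s), 0.4, 56, cp)
  expect_equal(tr$volumes_mL, oracle, tolerance = 1e-12)
  # frozen value from the ledger recursion:
  # V_1 = 1120/58.8, amount after sampling = (V_1 - 0.4)*58.8 + 0.4*56
  #     = 1118.88 -> V_2 = 1118.88/61.6
  expect_equal(tr$volumes_mL[2], 18.163636363636364, tolerance = 1e-9)
})

test_that("literal and recursive variants agree at t = 1 and under no flux", {
  cp <- c(56, 58.8, 61.6, 63.1)
  s <- make_series(cp)
  lit <- volume_trace(s, "literal")
  rec <- volume_trace(s, "recursive")
  expect_equal(lit$volumes_mL[1], rec$volumes_mL[1])
  # rising marker concentrations mean volume was lost; the literal form
  # re-credits V_0 every step so it can only overestimate
  expect_true(all(lit$volumes_mL[-1] >= rec$volumes_mL[-1]))
  expect_lt(max(lit$volumes_mL - rec$volumes_mL),
            rec$v0_mL - min(rec$volumes_mL))

  const <- make_series(rep(56, 4))
  expect_equal(volume_trace(const, "literal")$volumes_mL, rep(20, 3))
  expect_equal(volume_trace(const, "recursive")$volumes_mL, rep(20, 3))
})

test_that("recursive trace recovers the simulator's true volumes exactly", {
  d <- perfusion_design(true_jwater_uL_per_cm_per_h = 250)
  run <- simulate_perfusion_run(geom, d, ideal_marker(), test_drug())
  tr <- volume_trace(run$observations, "recursive")
  expect_lt(rel_err(tr$v0_mL, run$truth$volumes_mL[1]), 1e-9)
  expect_lt(max(rel_err(tr$volumes_mL, run$truth$volumes_mL[-1])), 1e-9)
})

test_that("corrected concentrations rescale by the volume ratio", {
  s <- make_series(c(56, 58.8, 61.6, 63.1), drug_conc = c(90, 85, 80))
  tr <- volume_trace(s)
  expect_equal(corrected_concentrations(s, tr),
               c(90, 85, 80) * tr$volumes_mL / tr$v0_mL)
  # identity when no volume change
  s2 <- make_series(rep(56, 4), drug_conc = c(90, 85, 80))
  expect_equal(corrected_concentrations(s2, volume_trace(s2)), c(90, 85, 80))
  # hand value: C_e = 90, V_t/V_0 = 18/20 -> 81
  expect_equal(90 * 18 / 20, 81)
})

test_that("volume correction cancels concentration rise from water flux", {
  # strong water absorption, drug that is not absorbed, negligible sampling
  d <- perfusion_design(true_jwater_uL_per_cm_per_h = 300,
                        sample_volume_mL = 1e-6)
  run <- simulate_perfusion_run(geom, d, ideal_marker(), test_drug(0))
  raw <- run$observations$drug_concentrations_uM
  expect_gt(max(raw) / min(raw), 1.05) # uncorrected drifts upward
  ct <- corrected_concentrations(run$observations,
                                 volume_trace(run$observations))
  expect_lt(max(ct) / min(ct) - 1, 1e-6) # corrected is flat
})

test_that("ka fit is exact on exponentials and handles edge cases", {
  t <- seq(10, 60, by = 10)
  fit <- fit_ka(t, 100 * exp(-0.01 * t))
  expect_equal(fit$ka_per_min, 0.01, tolerance = 1e-12)
  expect_equal(fit$c0_fit_uM, 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  expect_equal(fit_ka(t, rep(50, 6))$ka_per_min, 0)

  expect_warning(f2 <- fit_ka(t, c(100, 90, 0, 80, 70, 60)), "excluded")
  expect_equal(f2$n_points_used, 5L)
  suppressWarnings(expect_error(fit_ka(t[1:3], c(1, 0, 0)), "at least 3"))

  # window restricts the fit
  y <- c(100 * exp(-0.02 * t[1:3]), 100 * exp(-0.01 * t[4:6]))
  f3 <- fit_ka(t, y, window = c(10, 30))
  expect_equal(f3$ka_per_min, 0.02, tolerance = 1e-12)
})

test_that("Peff conversion is the exact inverse of the simulated rate", {
  g2 <- segment_geometry("jejunum", radius_cm = 0.2)
  # ka = 1e-3 /s = 0.06 /min, R = 0.2 cm -> Peff = 1e-4 cm/s
  expect_equal(peff_from_ka(0.06, g2), 1e-4)
  expect_equal(peff_from_ka(0, g2), 0)
  expect_equal(rate_to_permeability(permeability_to_rate(2.5e-5, 0.18), 0.18),
               2.5e-5)
})

test_that("water flux regression converts units correctly", {
  tr <- structure(list(v0_mL = 20, volumes_mL = 20 - 0.025 * c(10, 20, 30),
                       times_min = c(10, 20, 30), variant = "recursive"),
                  class = "volume_trace")
  wf <- water_flux(tr, geometry = geom) # L = 10 cm
  expect_equal(wf$jwater_uL_per_cm_per_h, 150, tolerance = 1e-12)
  expect_equal(wf$jwater_endpoint_uL_per_cm_per_h, 150, tolerance = 1e-12)
  expect_equal(wf$r_squared, 1)

  flat <- structure(list(v0_mL = 20, volumes_mL = rep(20, 3),
                         times_min = c(10, 20, 30), variant = "recursive"),
                    class = "volume_trace")
  expect_equal(water_flux(flat, geometry = geom)$jwater_uL_per_cm_per_h, 0)
})

test_that("full chain recovers truth as sample volume and noise vanish", {
  d <- perfusion_design(sample_volume_mL = 1e-6,
                        true_jwater_uL_per_cm_per_h = 150)
  for (p in c(2.5e-5, 1e-4)) {
    run <- simulate_perfusion_run(geom, d, ideal_marker(), test_drug(p))
    res <- analyze_perfusion(run$observations)
    expect_lt(rel_err(res$peff_cm_per_s, p), 0.001)
    expect_lt(rel_err(res$jwater$jwater_uL_per_cm_per_h, 150), 0.001)
    expect_equal(res$peff_cm_per_s,
                 rate_to_permeability(res$ka_fit$ka_per_min, geom$radius_cm))
  }
})

test_that("sampling dilution biases ka by exactly ln(1/(1 - s/V))/dt when V is constant", {
  # no water flux, ideal marker: every sampling+replacement multiplies the
  # drug concentration by (1 - s/V') with V' fixed, so the log-linear fit
  # picks up the analytic offset exactly
  d <- perfusion_design(true_jwater_uL_per_cm_per_h = 0)
  run <- simulate_perfusion_run(geom, d, ideal_marker(), test_drug(2.5e-5))
  res <- analyze_perfusion(run$observations)
  ka_true <- permeability_to_rate(2.5e-5, geom$radius_cm)
  predicted_bias <- -log(1 - 0.4 / 20) / 10
  expect_equal(res$ka_fit$ka_per_min - ka_true, predicted_bias,
               tolerance = 1e-9)
})

test_that("marker absorption biases Jwater downward, monotonically in Papp", {
  d <- perfusion_design(true_jwater_uL_per_cm_per_h = 200)
  jw <- vapply(c(1e-7, 5e-7, 1e-6, 5e-6), function(pm) {
    run <- simulate_perfusion_run(geom, d, pr_marker(pm), test_drug())
    analyze_perfusion(run$observations)$jwater$jwater_uL_per_cm_per_h
  }, numeric(1))
  expect_true(all(jw < 200))
  expect_true(all(diff(jw) < 0)) # more marker absorption, lower estimate
})

test_that("noisy cohort recovers ka within 5% in the median at n = 6", {
  st <- study_descriptor("perfusion", geom,
                         perfusion_design(sample_volume_mL = 1e-3,
                                          true_jwater_uL_per_cm_per_h = 150),
                         marker = ideal_marker(),
                         drug = test_drug(1e-4))
  cohort <- generate_cohort(st, 6, noise_model(assay_cv = 0.05, seed = 17))
  ka <- vapply(cohort, function(r) {
    analyze_perfusion(r$observations)$ka_fit$ka_per_min
  }, numeric(1))
  expect_lt(rel_err(median(ka), permeability_to_rate(1e-4, geom$radius_cm)),
            0.05)
})

test_that("series validation catches malformed inputs", {
  expect_error(perfusion_series(c(0, 10, 20), c(56, 57, 58), c(90, 80, 70),
                                56, 20, 100, 0.4, geom), "one element longer")
  expect_error(perfusion_series(c(10, 20, 30), c(56, 57, 58), c(90, 80),
                                56, 20, 100, 0.4, geom), "start at 0")
  expect_error(make_series(c(56, -1, 58, 60)), "> 0")
})
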