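geom <- segment_geometry("jejunum")

test_that("cumulative amounts restore the sampled-away fractions", {
  s <- egs_series(c(15, 30, 45), c(1, 2, 3), sac_volume_mL = 2,
                  sample_volume_mL = 0.4, donor_concentration_uM = 56, geom)
  expect_equal(cumulative_amounts(s), c(2.0, 4.4, 7.2))

  z <- egs_series(c(15, 30, 45), c(0, 0, 0), 2, 0.4, 56, geom)
  expect_equal(cumulative_amounts(z), c(0, 0, 0))
})

test_that("cumulative amounts equal the simulator's true transfer exactly", {
  for (sink in c(TRUE, FALSE)) {
    for (depl in c(TRUE, FALSE)) {
      d <- egs_design(sink_assumption = sink, donor_depletion = depl)
      run <- simulate_egs_run(geom, d, pr_marker(5e-6))
      Q <- cumulative_amounts(run$observations)
      expect_lt(max(rel_err(Q, run$truth$cumulative_transfer_nmol)), 1e-9)
      expect_true(all(diff(Q) > 0)) # non-decreasing under positive flux
    }
  }
})

test_that("Papp is exact for linear Q and recovers simulated truth", {
  # concentrations constructed so that Q_n = m * t_n exactly ->
  # Papp = m / (A C0) to machine precision
  t <- c(15, 30, 45, 60)
  m <- 0.19 # nmol/min
  V <- 2
  sv <- 0.4
  conc <- numeric(4)
  for (i in seq_along(t)) {
    conc[i] <- (m * t[i] - sv * sum(conc[seq_len(i - 1)])) / V
  }
  s <- egs_series(t, conc, V, sv, 56, geom)
  expect_equal(cumulative_amounts(s), m * t)
  fit <- apparent_permeability(s)
  expect_equal(fit$flux_nmol_per_min, m, tolerance = 1e-12)
  expect_equal(fit$papp_cm_per_s, m / (surface_area(geom) * 56) / 60,
               tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  # sink-condition, constant-donor, noise-free run: recovery within 0.5%
  run <- simulate_egs_run(geom, egs_design(donor_depletion = FALSE),
                          pr_marker(5e-6))
  est <- apparent_permeability(run$observations)
  expect_lt(rel_err(est$papp_cm_per_s, 5e-6), 0.005)
  expect_gt(est$r_squared, 0.9999)
})

test_that("Papp recovery is concentration-invariant (28/56/112 uM)", {
  papps <- vapply(c(28, 56, 112), function(c0) {
    run <- simulate_egs_run(geom, egs_design(), pr_marker(5e-6, conc = c0))
    apparent_permeability(run$observations)$papp_cm_per_s
  }, numeric(1))
  expect_lt(max(papps) / min(papps) - 1, 0.01)
})

test_that("cumulative fraction follows the permeability ratio across markers", {
  w <- vapply(c(5e-6, 3e-7), function(p) {
    run <- simulate_egs_run(geom, egs_design(), pr_marker(p))
    cumulative_fraction(run$observations, reference_volume_mL = 20)
  }, numeric(1))
  expect_gt(w[1], w[2])
  # near-linear regime: W scales with Papp up to the depletion nonlinearity
  expect_lt(rel_err(w[1] / w[2], 5e-6 / 3e-7), 0.05)
})

test_that("cumulative fraction arithmetic and conventions", {
  s <- egs_series(c(15, 30), c(2.4, 5.12), 2, 0.4, 56, geom)
  Q <- cumulative_amounts(s) # Q_2 = 5.12*2 + 0.4*2.4 = 11.2 nmol
  expect_equal(Q[2], 11.2)
  expect_equal(cumulative_fraction(s, reference_volume_mL = 20), 1.0)
  # literal convention divides by the sac volume instead
  expect_equal(cumulative_fraction(s, literal = TRUE), 10.0)
  expect_error(cumulative_fraction(s), "reference_volume")
})

test_that("estimator preconditions are enforced", {
  s2 <- egs_series(c(15, 30), c(1, 2), 2, 0.4, 56, geom)
  expect_error(apparent_permeability(s2), "at least 3")
  expect_error(egs_series(c(15, 10), c(1, 2), 2, 0.4, 56, geom), "increasing")
  expect_error(egs_series(c(15, 30), c(-1, 2), 2, 0.4, 56, geom), ">= 0")
})
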