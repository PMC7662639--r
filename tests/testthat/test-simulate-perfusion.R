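test_that("no-flux identities: constant marker, pure exponential drug decay", {
  g <- segment_geometry("jejunum")
  # zero marker permeability + zero water flux + replacement with marker
  # stock keeps the marker at C' forever
  d <- perfusion_design(true_jwater_uL_per_cm_per_h = 0)
  run <- simulate_perfusion_run(g, d, ideal_marker(), test_drug(0))
  expect_equal(run$observations$marker_concentrations_uM, rep(56, 7))
  # the unabsorbed drug is diluted only by the marker-stock replacements:
  # a geometric factor (1 - s/V') per sampling event
  expect_equal(run$observations$drug_concentrations_uM,
               100 * (1 - 0.4 / 20)^(0:5), tolerance = 1e-12)

  # with no replacement at all, sampling removes volume and amount
  # proportionally, so the drug concentration is a pure exponential with the
  # rate implied by its permeability (here 0.01 /min -> C(60)/C0 = e^-0.6)
  d2 <- perfusion_design(true_jwater_uL_per_cm_per_h = 0,
                         replacement_policy = "none", stabilization_min = 0)
  p <- rate_to_permeability(0.01, g$radius_cm)
  run2 <- simulate_perfusion_run(g, d2, ideal_marker(), test_drug(p))
  times <- run2$observations$times_min[-1]
  expect_equal(run2$observations$drug_concentrations_uM,
               100 * exp(-0.01 * times), tolerance = 1e-12)
  expect_equal(run2$observations$drug_concentrations_uM[6] / 100,
               exp(-0.6), tolerance = 1e-12)
})

test_that("closed-form trajectory matches independent fourth-order integration", {
  g <- segment_geometry("jejunum")
  d <- perfusion_design(true_jwater_uL_per_cm_per_h = 150)
  mk <- pr_marker(5e-6)
  dg <- test_drug(2.5e-5)
  run <- simulate_perfusion_run(g, d, mk, dg)
  oracle <- rk4_perfusion_oracle(g, d, mk, dg)
  expect_lt(max(rel_err(run$truth$volumes_mL, oracle$volumes)), 1e-6)
  expect_lt(max(rel_err(run$truth$marker_concentrations_uM,
                        oracle$marker_conc)), 1e-6)
  expect_lt(max(rel_err(run$truth$drug_concentrations_uM,
                        oracle$drug_conc)), 1e-6)
})

test_that("mass balance closes to 1e-9 on noise-free runs across policies", {
  g <- segment_geometry("ileum")
  for (policy in c("marker_stock", "marker_and_drug_stock", "blank", "none")) {
    for (jw in c(0, 150, 300)) {
      d <- perfusion_design(replacement_policy = policy,
                            true_jwater_uL_per_cm_per_h = jw)
      run <- simulate_perfusion_run(g, d, pr_marker(1e-6), test_drug(5e-5))
      expect_lt(max(mass_balance_error(run)), 1e-9)
    }
  }
})

test_that("water absorption exhausting the perfusate fails naming the time", {
  g <- segment_geometry("jejunum")
  # q = 0.5 mL/min empties 20 mL to the 0.4-mL sample volume at 39.2 min
  d <- perfusion_design(true_jwater_uL_per_cm_per_h = 3000,
                        stabilization_min = 0)
  expect_error(
    simulate_perfusion_run(g, d, ideal_marker(), test_drug()),
    "exhausted.*39\\.2"
  )
})

test_that("same seed reproduces a run exactly; different seeds differ", {
  g <- segment_geometry("jejunum")
  d <- perfusion_design()
  a <- simulate_perfusion_run(g, d, pr_marker(), test_drug(),
                              noise_model(assay_cv = 0.05, seed = 11))
  b <- simulate_perfusion_run(g, d, pr_marker(), test_drug(),
                              noise_model(assay_cv = 0.05, seed = 11))
  c <- simulate_perfusion_run(g, d, pr_marker(), test_drug(),
                              noise_model(assay_cv = 0.05, seed = 12))
  expect_identical(a$observations, b$observations)
  expect_false(identical(a$observations$marker_concentrations_uM,
                         c$observations$marker_concentrations_uM))
})

test_that("trajectory is continuous in the water flux near zero", {
  g <- segment_geometry("jejunum")
  d0 <- perfusion_design(true_jwater_uL_per_cm_per_h = 0)
  deps <- perfusion_design(true_jwater_uL_per_cm_per_h = 1e-12)
  r0 <- simulate_perfusion_run(g, d0, pr_marker(1e-6), test_drug())
  reps <- simulate_perfusion_run(g, deps, pr_marker(1e-6), test_drug())
  expect_lt(max(rel_err(reps$truth$volumes_mL, r0$truth$volumes_mL)), 1e-8)
  expect_lt(max(rel_err(reps$truth$drug_concentrations_uM,
                        r0$truth$drug_concentrations_uM)), 1e-8)
})

test_that("invalid inputs are rejected", {
  expect_error(perfusion_design(sample_volume_mL = 25), "sample_volume")
  expect_error(perfusion_design(n_samples = 2), "n_samples")
  expect_error(solute_spec("x", "marker", -1e-6, 56), "permeability")
  expect_error(segment_geometry("jejunum", radius_cm = -1), "radius")
  expect_error(noise_model(assay_cv = -0.1), "CV")
})
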