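test_that("summaries use mean and sample SD", {
  expect_equal(summarize_values(c(1, 1, 1)), list(mean = 1, sd = 0, n = 3L))
  s <- summarize_values(c(2, 4))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-12)
  expect_true(is.na(summarize_values(5)$sd))
  expect_error(summarize_values(numeric(0)), "at least one")
})

test_that("group comparison handles identical and degenerate groups", {
  x <- c(1.1, 2.3, 0.7, 1.8, 1.2, 1.9)
  same <- compare_groups(x, x)
  expect_equal(same$t_p, 1)
  expect_false(same$significant_05)

  const <- compare_groups(rep(1, 4), rep(1, 4))
  expect_false(const$evaluable)
  expect_true(is.na(const$t_p))
  expect_true(is.na(const$shapiro_p[1]))

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("group comparison detects a 2-SD shift with high power", {
  set.seed(404)
  rejections <- vapply(seq_len(300), function(i) {
    compare_groups(rnorm(6), rnorm(6, mean = 2))$significant_05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)
})

null_config <- function(seed = 1L) {
  cfg <- default_study_config(seed = seed)
  for (m in names(cfg$markers)) cfg$markers[[m]]$papp_cm_per_s <- 0
  cfg$noise <- noise_model(seed = seed) # noise off
  cfg$n_animals_per_group <- 2L
  cfg$segments <- "jejunum"
  cfg$drugs <- cfg$drugs["atenolol-like"]
  cfg
}

test_that("null configuration: unbiased markers recover truth with zero spread", {
  res <- run_marker_comparison(null_config())
  # all markers ideal and noise off: every group recovers the same Jwater
  expect_equal(diff(range(res$summary$mean_jwater)), 0, tolerance = 1e-9)
  expect_lt(rel_err(res$summary$mean_jwater[1], 200), 1e-6)
  expect_equal(res$summary$sd_jwater, rep(0, 3), tolerance = 1e-12)
  expect_false(any(res$comparisons$evaluable)) # zero-variance comparisons

  pe <- run_peff_study(null_config())
  by_marker <- split(pe$summary$mean_peff, pe$summary$marker)
  expect_equal(by_marker[[1]], by_marker[[2]], tolerance = 1e-12)
  expect_equal(by_marker[[2]], by_marker[[3]], tolerance = 1e-12)
})

test_that("marker self-absorption orders the corrected estimates (no noise)", {
  cfg <- default_study_config()
  cfg$noise <- noise_model(seed = 1L)
  cfg$n_animals_per_group <- 2L
  cfg$segments <- "jejunum"
  cfg$drugs <- cfg$drugs["atenolol-like"]
  res <- run_marker_comparison(cfg)
  jw <- res$summary$mean_jwater[match(c("PR-like", "PEG4k-PR-like",
                                        "PEG5k-PR-like"), res$summary$marker)]
  expect_true(all(diff(jw) > 0))   # PR-like < PEG4k < PEG5k
  expect_true(all(jw <= 200))

  pe <- run_peff_study(cfg)
  peff <- pe$summary$mean_peff[match(c("PR-like", "PEG4k-PR-like",
                                       "PEG5k-PR-like"), pe$summary$marker)]
  expect_true(all(diff(peff) > 0))
})

test_that("study outputs are a pure function of (config, seed)", {
  cfg <- default_study_config(seed = 8)
  cfg$n_animals_per_group <- 2L
  cfg$segments <- "jejunum"
  cfg$drugs <- cfg$drugs["metoprolol-like"]
  a <- run_peff_study(cfg)
  b <- run_peff_study(cfg)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$comparisons, b$comparisons)
})

test_that("pipeline introduces no artifactual across-marker Peff difference", {
  # two ideal markers, assay noise only: the mean difference between the
  # marker-corrected Peff estimates should be centred at zero
  cfg <- default_study_config()
  cfg$markers <- list(A = list(concentration_uM = 56, papp_cm_per_s = 0),
                      B = list(concentration_uM = 56, papp_cm_per_s = 0))
  cfg$reference_marker <- "A"
  cfg$drugs <- cfg$drugs["metoprolol-like"]
  cfg$segments <- "jejunum"
  cfg$n_animals_per_group <- 2L
  diffs <- vapply(seq_len(200), function(k) {
    cfg$noise <- noise_model(assay_cv = 0.05, seed = 1000L + k)
    pe <- run_peff_study(cfg)
    mean(pe$estimates$peff_est[pe$estimates$marker == "A"]) -
      mean(pe$estimates$peff_est[pe$estimates$marker == "B"])
  }, numeric(1))
  scale <- 1.07e-4
  expect_lt(abs(mean(diffs)) / scale,
            3 * sd(diffs) / scale / sqrt(length(diffs)) + 1e-3)
})
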