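# Independent oracles and small fixture builders used across the test files.
# The integrators and ledgers here deliberately re-derive the protocol from
# first principles instead of calling the package's closed-form simulator.

# Classic fourth-order Runge-Kutta integration of the perfusion state
# (volume, marker amount, drug amount) with explicit sampling/replacement
# events, default 0.01-min steps.
rk4_perfusion_oracle <- function(geometry, design, marker, drug, step = 0.01) {
  R <- geometry$radius_cm
  L <- geometry$length_cm
  ka_m <- 2 * marker$permeability_cm_per_s / R * 60
  ka_d <- 2 * drug$permeability_cm_per_s / R * 60
  q <- design$true_jwater_uL_per_cm_per_h * L / 1000 / 60
  s <- design$sample_volume_mL
  cprime <- marker$initial_concentration_uM
  c0 <- drug$initial_concentration_uM

  deriv <- function(y) c(-q, -ka_m * y[2], -ka_d * y[3])
  integrate_over <- function(y, duration) {
    if (duration <= 0) return(y)
    nstep <- max(1L, ceiling(duration / step - 1e-9))
    h <- duration / nstep
    for (i in seq_len(nstep)) {
      k1 <- deriv(y)
      k2 <- deriv(y + h / 2 * k1)
      k3 <- deriv(y + h / 2 * k2)
      k4 <- deriv(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }

  y <- c(design$nominal_volume_mL, cprime * design$nominal_volume_mL, 0)
  y <- integrate_over(y, design$stabilization_min)

  n <- design$n_samples
  volumes <- numeric(n + 1)
  marker_conc <- numeric(n + 1)
  drug_conc <- numeric(n)
  volumes[1] <- y[1]
  marker_conc[1] <- y[2] / y[1]

  take_sample <- function(y) {
    frac <- s / y[1]
    c(y[1] - s, y[2] * (1 - frac), y[3] * (1 - frac))
  }
  y <- take_sample(y)
  y[1] <- y[1] + s
  if (design$t0_marker_in_replacement) y[2] <- y[2] + s * cprime
  y[3] <- c0 * y[1]

  for (k in seq_len(n)) {
    y <- integrate_over(y, design$sampling_interval_min)
    volumes[k + 1] <- y[1]
    marker_conc[k + 1] <- y[2] / y[1]
    drug_conc[k] <- y[3] / y[1]
    y <- take_sample(y)
    if (design$replacement_policy == "marker_stock") {
      y[1] <- y[1] + s
      y[2] <- y[2] + s * cprime
    } else if (design$replacement_policy == "marker_and_drug_stock") {
      y[1] <- y[1] + s
      y[2] <- y[2] + s * cprime
      y[3] <- y[3] + s * c0
    } else if (design$replacement_policy == "blank") {
      y[1] <- y[1] + s
    }
  }
  list(volumes = volumes, marker_conc = marker_conc, drug_conc = drug_conc)
}

# Step-by-step marker-amount ledger: the independent oracle for the
# recursive volume-trace estimator. `cp` holds the measured C'_0..C'_n.
ledger_volume_oracle <- function(v0, sample_volume, cprime, cp) {
  amount <- v0 * cp[1]
  vols <- numeric(length(cp) - 1)
  for (t in seq_along(vols)) {
    amount <- amount - sample_volume * cp[t] + sample_volume * cprime
    vols[t] <- amount / cp[t + 1]
  }
  vols
}

ideal_marker <- function(conc = 56) solute_spec("ideal-marker", "marker", 0, conc)
pr_marker <- function(p = 5e-6, conc = 56) solute_spec("PR-like", "marker", p, conc)
test_drug <- function(p = 2.5e-5, conc = 100, name = "drug") {
  solute_spec(name, "drug", p, conc)
}

rel_err <- function(est, truth) abs(est / truth - 1)

# small study config used by CLI/study determinism tests
write_small_config <- function(path, seed = 3L) {
  writeLines(c(
    "markers:",
    "  PR-like: {concentration_uM: 56, papp_cm_per_s: 5.0e-6}",
    "  PEG5k-PR-like: {concentration_uM: 56, papp_cm_per_s: 3.0e-7}",
    "drugs:",
    "  atenolol-like: {concentration_uM: 100, peff_cm_per_s: 2.5e-5}",
    "segments: [jejunum]",
    "n_animals_per_group: 3",
    "true_jwater_uL_per_cm_per_h: 200",
    "jwater_segment: jejunum",
    sprintf("noise: {assay_cv: 0.05, animal_cv_jwater: 0.3, animal_cv_permeability: 0.2, seed: %d}",
            seed)
  ), path)
  path
}
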