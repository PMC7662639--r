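#' Mean, SD and n of a group of estimates
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator), the
#' way parallel animal trials are conventionally summarized. SD is reported
#' as `NA` for a single value.
#'
#' @param values numeric vector, length >= 1; `NA`s are dropped.
#' @return list with `mean`, `sd`, `n`.
#' @examples
#' summarize_values(c(2, 4)) # mean 3, sd 1.414
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    stop("summarize_values needs at least one non-missing value", call. = FALSE)
  }
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Two-group comparison with normality check
#'
#' Per-group Shapiro-Wilk normality tests followed by a two-sample t-test
#' (Welch by default, pooled-variance optionally). Degenerate inputs (zero
#' variance in both groups, or groups too small to test) are reported as not
#' evaluable rather than raising an error, so a study can continue over the
#' remaining comparisons.
#'
#' @param a,b numeric vectors of per-animal estimates; `NA`s are dropped.
#' @param labels length-2 character vector naming the groups.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return an object of class `group_comparison`: group labels, `n`,
#'   `means`, `sds`, `shapiro_p` (NA when n < 3 or the group is constant),
#'   `t_p`, `welch`, `evaluable`, `significant_05`, `significant_01`.
#' @examples
#' compare_groups(rnorm(6, 100, 10), rnorm(6, 140, 10),
#'                labels = c("PR-like", "PEG5k-PR-like"))
#' @export
compare_groups <- function(a, b, labels = c("group1", "group2"),
                           var_equal = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  shapiro_one <- function(x) {
    if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  t_p <- tryCatch(
    stats::t.test(a, b, var.equal = var_equal)$p.value,
    error = function(e) NA_real_ # e.g. both groups essentially constant
  )
  evaluable <- !is.na(t_p)
  structure(
    list(labels = labels, n = c(length(a), length(b)),
         means = c(mean(a), mean(b)), sds = c(stats::sd(a), stats::sd(b)),
         shapiro_p = c(shapiro_one(a), shapiro_one(b)),
         t_p = t_p, welch = !var_equal, evaluable = evaluable,
         significant_05 = evaluable && t_p < 0.05,
         significant_01 = evaluable && t_p < 0.01),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d) vs %s (n=%d)\n",
              x$labels[1], x$n[1], x$labels[2], x$n[2]))
  cat(sprintf("  means %.4g +/- %.3g | %.4g +/- %.3g\n",
              x$means[1], x$sds[1], x$means[2], x$sds[2]))
  if (x$evaluable) {
    cat(sprintf("  %s t-test p = %.4g%s\n",
                if (x$welch) "Welch" else "pooled", x$t_p,
                if (x$significant_01) " (**)" else if (x$significant_05) " (*)" else ""))
  } else {
    cat("  comparison not evaluable (degenerate input)\n")
  }
  invisible(x)
}

as_comparison_row <- function(x, ...) {
  extra <- list(...)
  data.frame(
    extra,
    group_a = x$labels[1], group_b = x$labels[2],
    n_a = x$n[1], n_b = x$n[2],
    mean_a = x$means[1], sd_a = x$sds[1],
    mean_b = x$means[2], sd_b = x$sds[2],
    shapiro_p_a = x$shapiro_p[1], shapiro_p_b = x$shapiro_p[2],
    t_p = x$t_p, welch = x$welch, evaluable = x$evaluable,
    stringsAsFactors = FALSE
  )
}

#' Study configuration
#'
#' Scenario parameters for the comparative simulation studies: named marker
#' and drug scenarios with per-segment true permeabilities, the segments and
#' cohort size, the true water flux, the noise model, the shared perfusion
#' design, and analysis options. [default_study_config()] supplies
#' literature-typical rat values.
#'
#' @param markers named list; each element a list with `concentration_uM`
#'   and `papp_cm_per_s` (a single value or a named per-segment vector).
#' @param drugs named list; each element a list with `concentration_uM` and
#'   `peff_cm_per_s` (single value or named per-segment vector).
#' @param segments character vector of segments to study.
#' @param n_animals_per_group cohort size per group, >= 2.
#' @param true_jwater_uL_per_cm_per_h true net water flux shared by all
#'   scenarios.
#' @param noise a [noise_model()].
#' @param perfusion a [perfusion_design()] (its `true_jwater` field is
#'   overridden by `true_jwater_uL_per_cm_per_h`).
#' @param geometry_radius_cm effective lumen radius used for all segments.
#' @param reference_marker name of the marker group the others are compared
#'   against.
#' @param jwater_segment segment used for the water-flux comparison.
#' @param analysis list of options: `variant` (volume-trace variant),
#'   `window` (ka-fit window or NULL), `var_equal` (pooled t-test), `holm`
#'   (Holm-adjust p-values across comparisons).
#' @return an object of class `study_config`.
#' @export
study_config <- function(markers, drugs, segments = c("duodenum", "jejunum",
                                                      "ileum", "colon"),
                         n_animals_per_group = 6,
                         true_jwater_uL_per_cm_per_h = 200,
                         noise = noise_model(0.05, 0.4, 0.3, seed = 1L),
                         perfusion = perfusion_design(),
                         geometry_radius_cm = 0.18,
                         reference_marker = names(markers)[1],
                         jwater_segment = "jejunum",
                         analysis = list()) {
  stopifnot(is.list(markers), length(markers) >= 1, !is.null(names(markers)),
            is.list(drugs), length(drugs) >= 1, !is.null(names(drugs)),
            inherits(noise, "noise_model"),
            inherits(perfusion, "perfusion_design"))
  if (!is.numeric(n_animals_per_group) || n_animals_per_group < 2) {
    stop("n_animals_per_group must be >= 2", call. = FALSE)
  }
  if (!reference_marker %in% names(markers)) {
    stop("reference_marker must name one of the marker scenarios", call. = FALSE)
  }
  if (!jwater_segment %in% segments) {
    stop("jwater_segment must be one of the study segments", call. = FALSE)
  }
  defaults <- list(variant = "recursive", window = NULL, var_equal = FALSE,
                   holm = FALSE)
  analysis <- utils::modifyList(defaults, analysis)
  structure(
    list(markers = markers, drugs = drugs, segments = segments,
         n_animals_per_group = as.integer(n_animals_per_group),
         true_jwater_uL_per_cm_per_h = true_jwater_uL_per_cm_per_h,
         noise = noise, perfusion = perfusion,
         geometry_radius_cm = geometry_radius_cm,
         reference_marker = reference_marker,
         jwater_segment = jwater_segment, analysis = analysis),
    class = "study_config"
  )
}

#' Default study scenarios
#'
#' Literature-typical rat scenario values: a classical phenol-red-like marker
#' (Papp about 5e-6 cm/s) against two PEGylated low-permeability markers
#' (8e-7 and 3e-7 cm/s, roughly a 6-15-fold reduction), segmental trend
#' jejunum > duodenum > ileum > colon; three model drugs spanning the BCS
#' permeability range (a low-permeability paracellular drug near 2.5e-5
#' cm/s, and two high-permeability drugs near 1e-4 cm/s); true water flux
#' 200 uL/cm/h with 40% inter-animal CV, 30% CV on permeabilities and a 5%
#' assay CV.
#'
#' @param seed base seed stored in the noise model.
#' @return a [study_config()].
#' @export
default_study_config <- function(seed = 1L) {
  seg_scale <- c(duodenum = 0.9, jejunum = 1, ileum = 0.7, colon = 0.5)
  study_config(
    markers = list(
      "PR-like" = list(concentration_uM = 56,
                       papp_cm_per_s = 5e-6 * seg_scale),
      "PEG4k-PR-like" = list(concentration_uM = 56,
                             papp_cm_per_s = 8e-7 * seg_scale),
      "PEG5k-PR-like" = list(concentration_uM = 56,
                             papp_cm_per_s = 3e-7 * seg_scale)
    ),
    drugs = list(
      "atenolol-like" = list(concentration_uM = 100,
                             peff_cm_per_s = c(duodenum = 2.5e-5,
                                               jejunum = 2.6e-5,
                                               ileum = 2.3e-5,
                                               colon = 3.3e-5)),
      "ketoprofen-like" = list(concentration_uM = 100,
                               peff_cm_per_s = c(duodenum = 1.0e-4,
                                                 jejunum = 1.0e-4,
                                                 ileum = 1.11e-4,
                                                 colon = 1.29e-4)),
      "metoprolol-like" = list(concentration_uM = 100,
                               peff_cm_per_s = c(duodenum = 1.0e-4,
                                                 jejunum = 1.07e-4,
                                                 ileum = 9.4e-5,
                                                 colon = 1.02e-4))
    ),
    noise = noise_model(0.05, 0.4, 0.3, seed = seed)
  )
}

scenario_value <- function(x, segment) {
  if (length(x) == 1 && is.null(names(x))) return(unname(x))
  if (!segment %in% names(x)) {
    stop(sprintf("no scenario value for segment '%s'", segment), call. = FALSE)
  }
  unname(x[[segment]])
}

config_geometry <- function(config, segment) {
  segment_geometry(segment, radius_cm = config$geometry_radius_cm)
}

marker_spec <- function(config, marker_name, segment) {
  m <- config$markers[[marker_name]]
  solute_spec(marker_name, "marker",
              scenario_value(m$papp_cm_per_s, segment), m$concentration_uM)
}

drug_spec <- function(config, drug_name, segment) {
  d <- config$drugs[[drug_name]]
  solute_spec(drug_name, "drug",
              scenario_value(d$peff_cm_per_s, segment), d$concentration_uM)
}

# simulate one cohort and estimate per-animal (Peff, Jwater); estimation
# failures are recorded as NA with the message kept, and the study continues
estimate_cohort <- function(config, marker_name, drug_name, segment, seed,
                            run_prefix = "run") {
  geometry <- config_geometry(config, segment)
  design <- config$perfusion
  design$true_jwater_uL_per_cm_per_h <- config$true_jwater_uL_per_cm_per_h
  noise <- config$noise
  noise$seed <- seed
  st <- study_descriptor("perfusion", geometry, design,
                         marker = marker_spec(config, marker_name, segment),
                         drug = drug_spec(config, drug_name, segment))
  cohort <- generate_cohort(st, config$n_animals_per_group, noise,
                            run_prefix = run_prefix)
  rows <- lapply(seq_along(cohort), function(i) {
    run <- cohort[[i]]
    res <- tryCatch(
      analyze_perfusion(run$observations, variant = config$analysis$variant,
                        window = config$analysis$window),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      data.frame(marker = marker_name, drug = drug_name, segment = segment,
                 run_id = run$run_id,
                 peff_est = NA_real_, jwater_est = NA_real_,
                 peff_true = run$truth$peff_cm_per_s,
                 jwater_true = run$truth$jwater_uL_per_cm_per_h,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(marker = marker_name, drug = drug_name, segment = segment,
                 run_id = run$run_id,
                 peff_est = res$peff_cm_per_s,
                 jwater_est = res$jwater$jwater_uL_per_cm_per_h,
                 peff_true = run$truth$peff_cm_per_s,
                 jwater_true = run$truth$jwater_uL_per_cm_per_h,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  list(estimates = do.call(rbind, rows), runs = cohort)
}

maybe_holm <- function(comparisons, holm) {
  if (holm && nrow(comparisons) > 0) {
    comparisons$t_p_adjusted <- stats::p.adjust(comparisons$t_p, "holm")
  }
  comparisons
}

#' Marker comparison for water flux
#'
#' Simulates one cohort per marker scenario with an identical true water
#' flux, estimates Jwater per animal through the full correction chain, and
#' compares each low-permeability marker group against the reference
#' (classical) marker group. The more a marker is itself absorbed, the lower
#' its corrected Jwater — this is the bias the comparison quantifies.
#'
#' @param config a [study_config()].
#' @param seed base seed; defaults to the seed in the config's noise model.
#' @param keep_observations also return the tidy observation table of every
#'   simulated run (for writing result directories).
#' @return list of class `marker_comparison_study`: `estimates`
#'   (per-animal data frame), `summary` (per-marker mean/sd/n), and
#'   `comparisons` (one row per non-reference marker vs the reference);
#'   plus `observations` when requested.
#' @examples
#' res <- run_marker_comparison(default_study_config(seed = 42))
#' res$summary
#' @export
run_marker_comparison <- function(config, seed = config$noise$seed,
                                  keep_observations = FALSE) {
  stopifnot(inherits(config, "study_config"))
  segment <- config$jwater_segment
  drug_name <- names(config$drugs)[1]
  marker_names <- names(config$markers)
  est <- list()
  obs <- list()
  for (i in seq_along(marker_names)) {
    ec <- estimate_cohort(config, marker_names[i], drug_name, segment,
                          derive_seed(seed, i),
                          run_prefix = paste0("jw.", marker_names[i], ".r"))
    est[[i]] <- ec$estimates
    if (keep_observations) obs[[i]] <- observations_table(ec$runs)
  }
  estimates <- do.call(rbind, est)
  summary_df <- do.call(rbind, lapply(marker_names, function(m) {
    sm <- summarize_values(estimates$jwater_est[estimates$marker == m])
    data.frame(marker = m, segment = segment, mean_jwater = sm$mean,
               sd_jwater = sm$sd, n = sm$n,
               true_jwater = config$true_jwater_uL_per_cm_per_h,
               stringsAsFactors = FALSE)
  }))
  ref <- config$reference_marker
  others <- setdiff(marker_names, ref)
  comparisons <- do.call(rbind, lapply(others, function(m) {
    cmp <- compare_groups(estimates$jwater_est[estimates$marker == ref],
                          estimates$jwater_est[estimates$marker == m],
                          labels = c(ref, m),
                          var_equal = config$analysis$var_equal)
    as_comparison_row(cmp, quantity = "jwater", segment = segment)
  }))
  comparisons <- maybe_holm(comparisons, config$analysis$holm)
  out <- list(estimates = estimates, summary = summary_df,
              comparisons = comparisons, seed = seed)
  if (keep_observations) out$observations <- do.call(rbind, obs)
  structure(out, class = "marker_comparison_study")
}

#' Factorial Peff study across drugs, segments and markers
#'
#' Simulates the full drug x segment x marker factorial, estimates Peff per
#' animal through the correction chain, summarizes each cell, and compares
#' the Peff corrected by each low-permeability marker against the reference
#' marker within every (drug, segment) cell.
#'
#' @inheritParams run_marker_comparison
#' @return list of class `peff_study`: `estimates`, `summary` (per cell),
#'   `comparisons`; plus `observations` when requested.
#' @export
run_peff_study <- function(config, seed = config$noise$seed,
                           keep_observations = FALSE) {
  stopifnot(inherits(config, "study_config"))
  marker_names <- names(config$markers)
  est <- list()
  obs <- list()
  idx <- 0
  for (d in names(config$drugs)) {
    for (sg in config$segments) {
      for (m in marker_names) {
        idx <- idx + 1
        ec <- estimate_cohort(config, m, d, sg, derive_seed(seed, idx),
                              run_prefix = paste0("peff.", m, ".", d, ".",
                                                  sg, ".r"))
        est[[idx]] <- ec$estimates
        if (keep_observations) obs[[idx]] <- observations_table(ec$runs)
      }
    }
  }
  estimates <- do.call(rbind, est)
  cells <- unique(estimates[c("drug", "segment", "marker")])
  summary_df <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- estimates$drug == cells$drug[i] &
      estimates$segment == cells$segment[i] &
      estimates$marker == cells$marker[i]
    sm <- summarize_values(estimates$peff_est[sel])
    data.frame(cells[i, ], mean_peff = sm$mean, sd_peff = sm$sd, n = sm$n,
               true_peff = estimates$peff_true[sel][1],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  ref <- config$reference_marker
  others <- setdiff(marker_names, ref)
  comp <- list()
  idx <- 0
  for (d in names(config$drugs)) {
    for (sg in config$segments) {
      for (m in others) {
        sel_ref <- estimates$drug == d & estimates$segment == sg &
          estimates$marker == ref
        sel_m <- estimates$drug == d & estimates$segment == sg &
          estimates$marker == m
        cmp <- compare_groups(estimates$peff_est[sel_ref],
                              estimates$peff_est[sel_m],
                              labels = c(ref, m),
                              var_equal = config$analysis$var_equal)
        idx <- idx + 1
        comp[[idx]] <- as_comparison_row(cmp, quantity = "peff", drug = d,
                                         segment = sg)
      }
    }
  }
  comparisons <- maybe_holm(do.call(rbind, comp), config$analysis$holm)
  out <- list(estimates = estimates, summary = summary_df,
              comparisons = comparisons, seed = seed)
  if (keep_observations) out$observations <- do.call(rbind, obs)
  structure(out, class = "peff_study")
}
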