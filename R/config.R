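#' Load a study configuration from a YAML file
#'
#' Reads a structured key-value configuration (see the commented example
#' shipped at `system.file("extdata", "default_study.yaml", package =
#' "perfusim")`), validates it and returns a [study_config()]. Omitted
#' sections fall back to the package defaults.
#'
#' @param path path to a YAML configuration file.
#' @return a [study_config()].
#' @export
load_study_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  base <- default_study_config()

  markers <- if (!is.null(raw$markers)) {
    lapply(raw$markers, function(m) {
      list(concentration_uM = as.numeric(m$concentration_uM),
           papp_cm_per_s = unlist(m$papp_cm_per_s))
    })
  } else {
    base$markers
  }
  drugs <- if (!is.null(raw$drugs)) {
    lapply(raw$drugs, function(d) {
      list(concentration_uM = as.numeric(d$concentration_uM),
           peff_cm_per_s = unlist(d$peff_cm_per_s))
    })
  } else {
    base$drugs
  }

  noise <- if (!is.null(raw$noise)) {
    noise_model(
      assay_cv = raw$noise$assay_cv %||% 0,
      animal_cv_jwater = raw$noise$animal_cv_jwater %||% 0,
      animal_cv_permeability = raw$noise$animal_cv_permeability %||% 0,
      seed = raw$noise$seed %||% 1L
    )
  } else {
    base$noise
  }

  perfusion <- if (!is.null(raw$perfusion)) {
    p <- raw$perfusion
    perfusion_design(
      nominal_volume_mL = p$nominal_volume_mL %||% 20,
      sample_volume_mL = p$sample_volume_mL %||% 0.4,
      sampling_interval_min = p$sampling_interval_min %||% 10,
      n_samples = p$n_samples %||% 6,
      replacement_policy = p$replacement_policy %||% "marker_stock",
      stabilization_min = p$stabilization_min %||% 10,
      t0_marker_in_replacement = p$t0_marker_in_replacement %||% TRUE
    )
  } else {
    base$perfusion
  }

  analysis <- raw$analysis %||% list()
  if (!is.null(analysis$window)) analysis$window <- as.numeric(analysis$window)

  study_config(
    markers = markers,
    drugs = drugs,
    segments = raw$segments %||% base$segments,
    n_animals_per_group = raw$n_animals_per_group %||% base$n_animals_per_group,
    true_jwater_uL_per_cm_per_h = raw$true_jwater_uL_per_cm_per_h %||%
      base$true_jwater_uL_per_cm_per_h,
    noise = noise,
    perfusion = perfusion,
    geometry_radius_cm = raw$geometry_radius_cm %||% base$geometry_radius_cm,
    reference_marker = raw$reference_marker %||% names(markers)[1],
    jwater_segment = raw$jwater_segment %||% base$jwater_segment,
    analysis = analysis
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

config_echo_lines <- function(config) {
  c(
    sprintf("markers: %s", paste(names(config$markers), collapse = ", ")),
    sprintf("drugs: %s", paste(names(config$drugs), collapse = ", ")),
    sprintf("segments: %s", paste(config$segments, collapse = ", ")),
    sprintf("n_animals_per_group: %d", config$n_animals_per_group),
    sprintf("true_jwater_uL_per_cm_per_h: %g",
            config$true_jwater_uL_per_cm_per_h),
    sprintf("noise: assay_cv=%g animal_cv_jwater=%g animal_cv_permeability=%g",
            config$noise$assay_cv, config$noise$animal_cv_jwater,
            config$noise$animal_cv_permeability),
    sprintf("perfusion: V'=%g mL, s=%g mL, dt=%g min, n=%d, policy=%s",
            config$perfusion$nominal_volume_mL,
            config$perfusion$sample_volume_mL,
            config$perfusion$sampling_interval_min,
            config$perfusion$n_samples,
            config$perfusion$replacement_policy),
    sprintf("analysis: variant=%s, window=%s, var_equal=%s, holm=%s",
            config$analysis$variant,
            if (is.null(config$analysis$window)) "all" else
              paste(config$analysis$window, collapse = "-"),
            config$analysis$var_equal, config$analysis$holm)
  )
}
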