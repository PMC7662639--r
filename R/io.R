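#' Tidy observation tables
#'
#' Simulated (or imported) measurements are exchanged as a tidy table with
#' one row per measured concentration and columns `run_id`,
#' `experiment_type`, `segment`, `time_min`, `analyte`, `concentration_uM`.
#' `observations_table()` builds the table from simulated runs;
#' `truth_table()` extracts the parallel per-run ground truth.
#'
#' @param runs a `simulated_run` or a list of them.
#' @return a data frame.
#' @export
observations_table <- function(runs) {
  if (inherits(runs, "simulated_run")) runs <- list(runs)
  do.call(rbind, lapply(runs, function(run) {
    if (run$experiment == "perfusion") {
      obs <- run$observations
      rbind(
        data.frame(run_id = run$run_id, experiment_type = "perfusion",
                   segment = run$geometry$segment,
                   time_min = obs$times_min, analyte = run$marker$name,
                   concentration_uM = obs$marker_concentrations_uM,
                   stringsAsFactors = FALSE),
        data.frame(run_id = run$run_id, experiment_type = "perfusion",
                   segment = run$geometry$segment,
                   time_min = obs$times_min[-1], analyte = run$drug$name,
                   concentration_uM = obs$drug_concentrations_uM,
                   stringsAsFactors = FALSE)
      )
    } else {
      obs <- run$observations
      data.frame(run_id = run$run_id, experiment_type = "egs",
                 segment = run$geometry$segment,
                 time_min = obs$times_min, analyte = run$solute$name,
                 concentration_uM = obs$receiver_concentrations_uM,
                 stringsAsFactors = FALSE)
    }
  }))
}

#' @rdname observations_table
#' @export
truth_table <- function(runs) {
  if (inherits(runs, "simulated_run")) runs <- list(runs)
  do.call(rbind, lapply(runs, function(run) {
    if (run$experiment == "perfusion") {
      data.frame(run_id = run$run_id, experiment_type = "perfusion",
                 segment = run$geometry$segment,
                 jwater_true_uL_per_cm_per_h = run$truth$jwater_uL_per_cm_per_h,
                 peff_true_cm_per_s = run$truth$peff_cm_per_s,
                 marker_papp_true_cm_per_s = run$truth$marker_papp_cm_per_s,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(run_id = run$run_id, experiment_type = "egs",
                 segment = run$geometry$segment,
                 jwater_true_uL_per_cm_per_h = NA_real_,
                 peff_true_cm_per_s = NA_real_,
                 marker_papp_true_cm_per_s = run$truth$papp_cm_per_s,
                 stringsAsFactors = FALSE)
    }
  }))
}

obs_columns <- c("run_id", "experiment_type", "segment", "time_min",
                 "analyte", "concentration_uM")

#' Read and write observation tables
#'
#' Plain UTF-8 comma-separated files with a dot decimal separator; numbers
#' are written with full precision (15 significant digits) so a round trip
#' does not perturb downstream fits. `read_observations()` validates the
#' schema and value ranges and reports offending rows.
#'
#' @param observations a data frame in the observation schema.
#' @param path file path.
#' @return `read_observations()` returns the validated data frame;
#'   `write_observations()` returns `path` invisibly.
#' @export
write_observations <- function(observations, path) {
  validate_observations(observations)
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("observation file not found: %s", path), call. = FALSE)
  }
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observations(obs)
}

validate_observations <- function(obs) {
  missing <- setdiff(obs_columns, names(obs))
  if (length(missing) > 0) {
    stop(sprintf("observation table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(obs$time_min) || !is.numeric(obs$concentration_uM)) {
    stop("time_min and concentration_uM must be numeric", call. = FALSE)
  }
  bad <- which(obs$time_min < 0)
  if (length(bad) > 0) {
    stop(sprintf("negative time_min in row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  bad <- which(obs$concentration_uM < 0)
  if (length(bad) > 0) {
    stop(sprintf("negative concentration_uM in row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  key <- paste(obs$run_id, obs$time_min, obs$analyte, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf("duplicate (run_id, time_min, analyte) in row(s): %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  obs
}

#' Rebuild a perfusion series from an observation table
#'
#' Extracts one run's marker and drug rows from a tidy observation table and
#' assembles the [perfusion_series()] needed by [analyze_perfusion()]. The
#' nominal design constants (C', V', C_0, sample volume) are not part of the
#' observation schema and must be supplied.
#'
#' @param observations observation data frame.
#' @param run_id run to extract.
#' @param marker_name,drug_name analyte names of the marker and the drug.
#' @param design a [perfusion_design()] supplying V' and the sample volume.
#' @param marker_concentration_uM,drug_concentration_uM nominal C' and C_0.
#' @param geometry a [segment_geometry()]; defaults to the run's segment
#'   with default dimensions.
#' @return a [perfusion_series()].
#' @export
series_from_observations <- function(observations, run_id, marker_name,
                                     drug_name, design,
                                     marker_concentration_uM,
                                     drug_concentration_uM,
                                     geometry = NULL) {
  validate_observations(observations)
  rows <- observations[observations$run_id == run_id, ]
  if (nrow(rows) == 0) {
    stop(sprintf("no rows for run_id '%s'", run_id), call. = FALSE)
  }
  mk <- rows[rows$analyte == marker_name, ]
  dg <- rows[rows$analyte == drug_name, ]
  if (nrow(mk) == 0) {
    stop(sprintf("run '%s' has no rows for marker analyte '%s'", run_id,
                 marker_name), call. = FALSE)
  }
  if (nrow(dg) == 0) {
    stop(sprintf("run '%s' has no rows for drug analyte '%s'", run_id,
                 drug_name), call. = FALSE)
  }
  mk <- mk[order(mk$time_min), ]
  dg <- dg[order(dg$time_min), ]
  if (is.null(geometry)) geometry <- segment_geometry(rows$segment[1])
  perfusion_series(
    times_min = mk$time_min,
    marker_concentrations_uM = mk$concentration_uM,
    drug_concentrations_uM = dg$concentration_uM,
    nominal_marker_concentration_uM = marker_concentration_uM,
    nominal_volume_mL = design$nominal_volume_mL,
    nominal_drug_concentration_uM = drug_concentration_uM,
    sample_volume_mL = design$sample_volume_mL,
    geometry = geometry
  )
}

#' @rdname series_from_observations
#' @param egs_design_obj an [egs_design()] supplying the sac and sample
#'   volumes.
#' @param analyte analyte name of the EGS solute.
#' @param donor_concentration_uM nominal donor concentration C_0.
#' @export
egs_series_from_observations <- function(observations, run_id, analyte,
                                         egs_design_obj,
                                         donor_concentration_uM,
                                         geometry = NULL) {
  validate_observations(observations)
  rows <- observations[observations$run_id == run_id &
                         observations$analyte == analyte, ]
  if (nrow(rows) == 0) {
    stop(sprintf("run '%s' has no rows for analyte '%s'", run_id, analyte),
         call. = FALSE)
  }
  rows <- rows[order(rows$time_min), ]
  if (is.null(geometry)) geometry <- segment_geometry(rows$segment[1])
  egs_series(
    times_min = rows$time_min,
    receiver_concentrations_uM = rows$concentration_uM,
    sac_volume_mL = egs_design_obj$sac_volume_mL,
    sample_volume_mL = egs_design_obj$sample_volume_mL,
    donor_concentration_uM = donor_concentration_uM,
    geometry = geometry
  )
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run log
#'
#' Writes a small plain-text log (seed, package version, config echo,
#' warnings) next to analysis outputs so every result directory is
#' traceable to the seed and configuration that produced it.
#'
#' @param path file path for the log.
#' @param seed seed used.
#' @param config_echo character vector echoing the configuration.
#' @param warnings character vector of warnings to record.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, seed, config_echo = character(),
                          warnings = character()) {
  lines <- c(
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("perfusim version: %s",
            as.character(utils::packageVersion("perfusim"))),
    sprintf("seed: %d", as.integer(seed)),
    "config:",
    paste0("  ", config_echo)
  )
  if (length(warnings) > 0) {
    lines <- c(lines, "warnings:", paste0("  ", warnings))
  }
  writeLines(lines, path)
  invisible(path)
}
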