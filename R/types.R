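#' Intestinal segment geometry
#'
#' Effective lumen radius and perfused/everted length of an intestinal
#' segment. The radius enters twice: through the membrane surface area
#' `A = 2 pi R L` and through the cylindrical-lumen conversion
#' `Peff = ka * R / 2`. Rat radii are rarely reported; 0.18 cm is a typical
#' working value and segment lengths default to 10 cm (40 cm for the whole
#' small intestine).
#'
#' @param segment one of `"duodenum"`, `"jejunum"`, `"ileum"`, `"colon"`,
#'   `"whole_small_intestine"`.
#' @param radius_cm effective lumen radius R in cm, > 0.
#' @param length_cm perfused/everted length L in cm, > 0; default 10 cm
#'   (40 cm for the whole small intestine).
#' @return an object of class `segment_geometry`.
#' @examples
#' segment_geometry("jejunum")
#' segment_geometry("whole_small_intestine")$length_cm
#' @export
segment_geometry <- function(segment = c("jejunum", "duodenum", "ileum",
                                         "colon", "whole_small_intestine"),
                             radius_cm = 0.18, length_cm = NULL) {
  segment <- match.arg(segment)
  if (is.null(length_cm)) {
    length_cm <- if (segment == "whole_small_intestine") 40 else 10
  }
  if (!is.numeric(radius_cm) || length(radius_cm) != 1 || radius_cm <= 0) {
    stop("radius_cm must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(length_cm) || length(length_cm) != 1 || length_cm <= 0) {
    stop("length_cm must be a single positive number", call. = FALSE)
  }
  structure(
    list(segment = segment, radius_cm = radius_cm, length_cm = length_cm),
    class = "segment_geometry"
  )
}

#' @export
print.segment_geometry <- function(x, ...) {
  cat(sprintf("<segment_geometry> %s: R = %g cm, L = %g cm, A = %.2f cm^2\n",
              x$segment, x$radius_cm, x$length_cm, surface_area(x)))
  invisible(x)
}

#' Solute specification
#'
#' A marker or drug with its true membrane permeability and nominal
#' concentration. For a volume marker the permeability is the Papp one would
#' measure in an EGS assay (ideally 0); for a drug it is the effective
#' intestinal permeability Peff. Both are interpreted on the operational
#' cylindrical-lumen scale (`ka = 2 P / R`, see [permeability_to_rate()]).
#'
#' @param name solute label used in observation tables.
#' @param role `"marker"` or `"drug"`.
#' @param permeability_cm_per_s true permeability in cm/s, >= 0.
#' @param initial_concentration_uM nominal concentration in uM, > 0: the
#'   marker concentration C' of the perfusate, or the drug concentration C_0
#'   established at t = 0 (perfusion) / the donor concentration (EGS).
#' @return an object of class `solute_spec`.
#' @examples
#' solute_spec("PR-like", "marker", 5e-6, 56)
#' solute_spec("atenolol-like", "drug", 2.5e-5, 100)
#' @export
solute_spec <- function(name, role = c("marker", "drug"),
                        permeability_cm_per_s, initial_concentration_uM) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("name must be a nonempty string", call. = FALSE)
  }
  if (!is.numeric(permeability_cm_per_s) || length(permeability_cm_per_s) != 1 ||
      permeability_cm_per_s < 0) {
    stop("permeability_cm_per_s must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(initial_concentration_uM) ||
      length(initial_concentration_uM) != 1 || initial_concentration_uM <= 0) {
    stop("initial_concentration_uM must be a single number > 0", call. = FALSE)
  }
  structure(
    list(name = name, role = role,
         permeability_cm_per_s = permeability_cm_per_s,
         initial_concentration_uM = initial_concentration_uM),
    class = "solute_spec"
  )
}

#' Recirculation perfusion design
#'
#' Protocol constants of a recirculation perfusion run: a nominal perfusate
#' volume V' loaded with marker, a stabilization period, an initial marker
#' sample at t = 0 followed by a volume-restoring addition that introduces the
#' drug, then paired marker/drug samples every `sampling_interval_min` minutes
#' with the withdrawn volume replaced according to `replacement_policy`.
#'
#' @param nominal_volume_mL V', donor chamber + circuit volume in mL.
#' @param sample_volume_mL volume withdrawn per sampling event, mL; must be
#'   smaller than `nominal_volume_mL`.
#' @param sampling_interval_min minutes between samples, > 0.
#' @param n_samples number of post-t0 samples, >= 3.
#' @param replacement_policy what the withdrawn volume is replaced with at
#'   samplings after t = 0: `"marker_stock"` (marker at C', no drug; the
#'   default, matching the volume-trace estimator's marker re-addition term),
#'   `"marker_and_drug_stock"`, `"blank"`, or `"none"`.
#' @param true_jwater_uL_per_cm_per_h true net water absorption rate, per cm
#'   of intestine per hour; constant within a run (zero-order volume loss).
#'   May be negative (net secretion).
#' @param stabilization_min minutes of marker-only recirculation before the
#'   t = 0 sample; water (and any marker) absorption during this window is
#'   what the initial-volume correction picks up.
#' @param t0_marker_in_replacement does the 0.4-mL addition at t = 0 contain
#'   marker at C' (default TRUE, the reading under which the recursive volume
#'   trace conserves the assumed marker amount) or only drug?
#' @return an object of class `perfusion_design`.
#' @export
perfusion_design <- function(nominal_volume_mL = 20, sample_volume_mL = 0.4,
                             sampling_interval_min = 10, n_samples = 6,
                             replacement_policy = c("marker_stock",
                                                    "marker_and_drug_stock",
                                                    "blank", "none"),
                             true_jwater_uL_per_cm_per_h = 200,
                             stabilization_min = 10,
                             t0_marker_in_replacement = TRUE) {
  replacement_policy <- match.arg(replacement_policy)
  if (!is.numeric(nominal_volume_mL) || nominal_volume_mL <= 0) {
    stop("nominal_volume_mL must be > 0", call. = FALSE)
  }
  if (!is.numeric(sample_volume_mL) || sample_volume_mL <= 0 ||
      sample_volume_mL >= nominal_volume_mL) {
    stop("sample_volume_mL must be in (0, nominal_volume_mL)", call. = FALSE)
  }
  if (!is.numeric(sampling_interval_min) || sampling_interval_min <= 0) {
    stop("sampling_interval_min must be > 0", call. = FALSE)
  }
  if (!is.numeric(n_samples) || n_samples < 3 || n_samples != round(n_samples)) {
    stop("n_samples must be an integer >= 3", call. = FALSE)
  }
  if (!is.numeric(true_jwater_uL_per_cm_per_h) ||
      length(true_jwater_uL_per_cm_per_h) != 1) {
    stop("true_jwater_uL_per_cm_per_h must be a single number", call. = FALSE)
  }
  if (!is.numeric(stabilization_min) || stabilization_min < 0) {
    stop("stabilization_min must be >= 0", call. = FALSE)
  }
  structure(
    list(nominal_volume_mL = nominal_volume_mL,
         sample_volume_mL = sample_volume_mL,
         sampling_interval_min = sampling_interval_min,
         n_samples = as.integer(n_samples),
         replacement_policy = replacement_policy,
         true_jwater_uL_per_cm_per_h = true_jwater_uL_per_cm_per_h,
         stabilization_min = stabilization_min,
         t0_marker_in_replacement = isTRUE(t0_marker_in_replacement)),
    class = "perfusion_design"
  )
}

#' Everted gut sac design
#'
#' Protocol constants of an EGS run: an everted segment filled with blank
#' buffer (the receiver, volume V) incubated in a donor solution; every
#' `sampling_interval_min` minutes a receiver aliquot is withdrawn and
#' replaced with blank buffer.
#'
#' @param donor_volume_mL donor chamber volume, mL.
#' @param sac_volume_mL V, blank buffer injected into the everted sac, mL.
#' @param sample_volume_mL receiver aliquot withdrawn per sampling, mL; must
#'   be smaller than `sac_volume_mL`.
#' @param sampling_interval_min minutes between samples, > 0.
#' @param n_samples number of samples, >= 3.
#' @param sink_assumption if TRUE (default) the receiver concentration is
#'   neglected in the driving gradient.
#' @param donor_depletion if TRUE (default) the donor loses the transferred
#'   amount; FALSE holds the donor at its nominal concentration.
#' @return an object of class `egs_design`.
#' @export
egs_design <- function(donor_volume_mL = 20, sac_volume_mL = 2,
                       sample_volume_mL = 0.4, sampling_interval_min = 15,
                       n_samples = 8, sink_assumption = TRUE,
                       donor_depletion = TRUE) {
  if (!is.numeric(donor_volume_mL) || donor_volume_mL <= 0) {
    stop("donor_volume_mL must be > 0", call. = FALSE)
  }
  if (!is.numeric(sac_volume_mL) || sac_volume_mL <= 0) {
    stop("sac_volume_mL must be > 0", call. = FALSE)
  }
  if (!is.numeric(sample_volume_mL) || sample_volume_mL <= 0 ||
      sample_volume_mL >= sac_volume_mL) {
    stop("sample_volume_mL must be in (0, sac_volume_mL)", call. = FALSE)
  }
  if (!is.numeric(sampling_interval_min) || sampling_interval_min <= 0) {
    stop("sampling_interval_min must be > 0", call. = FALSE)
  }
  if (!is.numeric(n_samples) || n_samples < 3 || n_samples != round(n_samples)) {
    stop("n_samples must be an integer >= 3", call. = FALSE)
  }
  structure(
    list(donor_volume_mL = donor_volume_mL, sac_volume_mL = sac_volume_mL,
         sample_volume_mL = sample_volume_mL,
         sampling_interval_min = sampling_interval_min,
         n_samples = as.integer(n_samples),
         sink_assumption = isTRUE(sink_assumption),
         donor_depletion = isTRUE(donor_depletion)),
    class = "egs_design"
  )
}

#' Noise model
#'
#' Measurement and inter-animal variability. Assay noise is multiplicative
#' Gaussian on each measured concentration, with the relative deviation
#' clamped at -3 SD so measured concentrations stay positive for CV < 1/3.
#' Inter-animal variability is lognormal around the scenario means (fluxes
#' and permeabilities are positive), parameterized by coefficients of
#' variation on the natural scale.
#'
#' @param assay_cv relative SD of a single concentration measurement, >= 0.
#' @param animal_cv_jwater lognormal CV of the per-animal true water flux.
#' @param animal_cv_permeability lognormal CV of per-animal permeabilities.
#' @param seed integer base seed; identical seeds reproduce runs exactly.
#' @return an object of class `noise_model`.
#' @examples
#' noise_model()                       # noise-free, for oracle checks
#' noise_model(0.05, 0.4, 0.3, seed = 7)
#' @export
noise_model <- function(assay_cv = 0, animal_cv_jwater = 0,
                        animal_cv_permeability = 0, seed = 1L) {
  cvs <- c(assay_cv, animal_cv_jwater, animal_cv_permeability)
  if (!is.numeric(cvs) || any(cvs < 0)) {
    stop("all CVs must be >= 0", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  structure(
    list(assay_cv = assay_cv, animal_cv_jwater = animal_cv_jwater,
         animal_cv_permeability = animal_cv_permeability,
         seed = as.integer(seed)),
    class = "noise_model"
  )
}

# multiplicative assay factors: 1 + eps, eps ~ N(0, cv) clamped at -3 SD
assay_factors <- function(n, cv) {
  if (cv == 0 || n == 0) return(rep(1, n))
  1 + pmax(stats::rnorm(n, 0, cv), -3 * cv)
}

# lognormal draws with given arithmetic mean and CV; degenerate cases constant
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0 || mean <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
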