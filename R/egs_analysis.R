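#' Everted gut sac time series
#'
#' Measured receiver concentrations of an EGS run together with the design
#' constants needed by the estimators: the sac volume V, the withdrawn sample
#' volume, the donor concentration C_0 and the segment geometry.
#'
#' @param times_min strictly increasing sampling times, min.
#' @param receiver_concentrations_uM measured receiver concentrations
#'   C_1..C_n (>= 0), one per sampling time.
#' @param sac_volume_mL V, the blank buffer volume inside the sac.
#' @param sample_volume_mL aliquot withdrawn (and replaced with blank) at
#'   each sampling.
#' @param donor_concentration_uM C_0, donor chamber concentration.
#' @param geometry a [segment_geometry()].
#' @return an object of class `egs_series`.
#' @export
egs_series <- function(times_min, receiver_concentrations_uM, sac_volume_mL,
                       sample_volume_mL, donor_concentration_uM, geometry) {
  stopifnot(inherits(geometry, "segment_geometry"))
  if (length(times_min) != length(receiver_concentrations_uM)) {
    stop("times and concentrations must have equal length", call. = FALSE)
  }
  if (any(diff(times_min) <= 0)) {
    stop("times_min must be strictly increasing", call. = FALSE)
  }
  if (any(receiver_concentrations_uM < 0)) {
    stop("receiver concentrations must be >= 0", call. = FALSE)
  }
  if (sac_volume_mL <= 0 || sample_volume_mL <= 0 ||
      sample_volume_mL >= sac_volume_mL) {
    stop("need 0 < sample_volume_mL < sac_volume_mL", call. = FALSE)
  }
  if (donor_concentration_uM <= 0) {
    stop("donor_concentration_uM must be > 0", call. = FALSE)
  }
  structure(
    list(times_min = as.numeric(times_min),
         receiver_concentrations_uM = as.numeric(receiver_concentrations_uM),
         sac_volume_mL = sac_volume_mL, sample_volume_mL = sample_volume_mL,
         donor_concentration_uM = donor_concentration_uM,
         geometry = geometry),
    class = "egs_series"
  )
}

#' Replacement-corrected cumulative permeated amounts
#'
#' Reconstructs the cumulative amount transferred into the receiver from the
#' measured receiver concentrations, restoring the amounts carried away by
#' the periodic aliquot-for-blank exchanges:
#' `Q_n = C_n V + s * sum_{i=1}^{n-1} C_i` (nmol, with s the sample volume).
#' For receiver dynamics with any non-negative flux this undoes the sampling
#' dilution exactly.
#'
#' @param series an [egs_series()].
#' @return numeric vector Q_1..Q_n in nmol.
#' @examples
#' g <- segment_geometry("jejunum")
#' s <- egs_series(c(15, 30, 45), c(1, 2, 3), 2, 0.4, 56, g)
#' cumulative_amounts(s) # 2.0 4.4 7.2
#' @export
cumulative_amounts <- function(series) {
  stopifnot(inherits(series, "egs_series"))
  conc <- series$receiver_concentrations_uM
  conc * series$sac_volume_mL +
    series$sample_volume_mL * c(0, cumsum(conc)[-length(conc)])
}

#' Apparent permeability from an EGS time series
#'
#' `Papp = (dQ/dt) / (A C_0)` with the permeation rate `dQ/dt` taken as the
#' ordinary least-squares slope of the cumulative amounts Q versus time
#' (default: over all samples) and `A = 2 pi R L` (optionally scaled by an
#' area multiplier). Reported in cm/s.
#'
#' @param series an [egs_series()].
#' @param window optional `c(min, max)` time window (minutes, inclusive)
#'   restricting the points used in the regression.
#' @param area_multiplier dimensionless multiplier on the smooth-cylinder
#'   area, default 1.
#' @return an object of class `egs_result`: `papp_cm_per_s`,
#'   `flux_nmol_per_min` (dQ/dt), `r_squared`, `n_points_used`,
#'   `cumulative_amounts_nmol`.
#' @export
apparent_permeability <- function(series, window = NULL, area_multiplier = 1) {
  stopifnot(inherits(series, "egs_series"))
  Q <- cumulative_amounts(series)
  t <- series$times_min
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]
    Qw <- Q[keep]
  } else {
    Qw <- Q
  }
  if (length(t) < 3) {
    stop("apparent_permeability needs at least 3 time points", call. = FALSE)
  }
  A <- surface_area(series$geometry, area_multiplier)
  if (A <= 0 || series$donor_concentration_uM <= 0) {
    stop("surface area and donor concentration must be positive", call. = FALSE)
  }
  fit <- ols_fit(t, Qw)
  slope <- fit$slope # nmol/min
  papp <- slope / (A * series$donor_concentration_uM) / 60 # cm/min -> cm/s
  structure(
    list(papp_cm_per_s = papp, flux_nmol_per_min = slope,
         r_squared = fit$r_squared,
         n_points_used = length(t), cumulative_amounts_nmol = Q),
    class = "egs_result"
  )
}

#' Cumulative absorption percentage
#'
#' `W = Q_n / (V_ref C_0)`, expressed as a percentage: the fraction of the
#' reference amount of compound that permeated by the last sample. The
#' natural reference is the donor-chamber amount (`reference_volume_mL` =
#' donor volume); `literal = TRUE` instead uses the sac volume V as the
#' reference, reproducing the printed form of the classical formula (the two
#' conventions differ by the ratio of the volumes; see the methods vignette).
#'
#' @param series an [egs_series()].
#' @param reference_volume_mL reference volume in mL (usually the donor
#'   chamber volume); ignored when `literal = TRUE`.
#' @param literal use the sac volume V as the reference volume.
#' @return cumulative absorption W in percent.
#' @examples
#' g <- segment_geometry("jejunum")
#' s <- egs_series(c(15, 30, 45), c(1, 2, 3), 2, 0.4, 56, g)
#' cumulative_fraction(s, reference_volume_mL = 20)
#' @export
cumulative_fraction <- function(series, reference_volume_mL = NULL,
                                literal = FALSE) {
  stopifnot(inherits(series, "egs_series"))
  v_ref <- if (literal) series$sac_volume_mL else reference_volume_mL
  if (is.null(v_ref) || !is.numeric(v_ref) || v_ref <= 0) {
    stop("reference_volume_mL must be a positive number (or use literal = TRUE)",
         call. = FALSE)
  }
  Q <- cumulative_amounts(series)
  100 * Q[length(Q)] / (v_ref * series$donor_concentration_uM)
}

#' @export
print.egs_result <- function(x, ...) {
  cat(sprintf("<egs_result> Papp = %.4g cm/s (dQ/dt = %.4g nmol/min, r^2 = %.4f, n = %d)\n",
              x$papp_cm_per_s, x$flux_nmol_per_min, x$r_squared,
              x$n_points_used))
  invisible(x)
}
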