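#' Recirculation perfusion time series
#'
#' Measured marker and drug concentrations of a perfusion run, with the
#' design constants needed by the correction chain: the nominal marker
#' concentration C', the nominal circuit volume V', the nominal drug
#' concentration C_0 and the sample volume. The marker series has one more
#' element than the drug series (the t = 0 sample is marker-only).
#'
#' @param times_min sampling times starting at 0, strictly increasing.
#' @param marker_concentrations_uM measured marker concentrations
#'   C'_0..C'_n (> 0), one per time.
#' @param drug_concentrations_uM measured drug concentrations C_e at
#'   t_1..t_n.
#' @param nominal_marker_concentration_uM C', marker concentration of the
#'   loaded perfusate (and of the replacement stock).
#' @param nominal_volume_mL V', nominal perfusate volume.
#' @param nominal_drug_concentration_uM C_0, nominal drug concentration
#'   established at t = 0.
#' @param sample_volume_mL volume withdrawn (and replaced) per sampling.
#' @param geometry a [segment_geometry()].
#' @return an object of class `perfusion_series`.
#' @export
perfusion_series <- function(times_min, marker_concentrations_uM,
                             drug_concentrations_uM,
                             nominal_marker_concentration_uM,
                             nominal_volume_mL,
                             nominal_drug_concentration_uM,
                             sample_volume_mL, geometry) {
  stopifnot(inherits(geometry, "segment_geometry"))
  if (length(times_min) < 2 || times_min[1] != 0 || any(diff(times_min) <= 0)) {
    stop("times_min must be strictly increasing and start at 0", call. = FALSE)
  }
  if (length(marker_concentrations_uM) != length(times_min)) {
    stop("need one marker concentration per time point", call. = FALSE)
  }
  if (length(drug_concentrations_uM) != length(times_min) - 1) {
    stop("the marker series must be one element longer than the drug series",
         call. = FALSE)
  }
  if (any(marker_concentrations_uM <= 0)) {
    stop("marker concentrations must be > 0", call. = FALSE)
  }
  if (any(drug_concentrations_uM < 0)) {
    stop("drug concentrations must be >= 0", call. = FALSE)
  }
  if (nominal_marker_concentration_uM <= 0 || nominal_volume_mL <= 0 ||
      nominal_drug_concentration_uM <= 0 || sample_volume_mL <= 0) {
    stop("nominal concentrations, volume and sample volume must be > 0",
         call. = FALSE)
  }
  structure(
    list(times_min = as.numeric(times_min),
         marker_concentrations_uM = as.numeric(marker_concentrations_uM),
         drug_concentrations_uM = as.numeric(drug_concentrations_uM),
         nominal_marker_concentration_uM = nominal_marker_concentration_uM,
         nominal_volume_mL = nominal_volume_mL,
         nominal_drug_concentration_uM = nominal_drug_concentration_uM,
         sample_volume_mL = sample_volume_mL,
         geometry = geometry),
    class = "perfusion_series"
  )
}

#' Initial perfusate volume from the t = 0 marker sample
#'
#' `V_0 = C' V' / C'_0`: the marker amount loaded into the circuit is
#' `C' V'`; dividing by the measured t = 0 concentration recovers the volume
#' at the first sample, absorbing whatever water flux occurred during
#' stabilization.
#'
#' @param series a [perfusion_series()].
#' @return V_0 in mL.
#' @examples
#' # C' = 56 uM, V' = 20 mL, measured C'_0 = 58.8 uM -> 19.048 mL
#' 56 * 20 / 58.8
#' @export
initial_volume <- function(series) {
  stopifnot(inherits(series, "perfusion_series"))
  cp0 <- series$marker_concentrations_uM[1]
  if (cp0 <= 0) stop("C'_0 must be > 0", call. = FALSE)
  series$nominal_marker_concentration_uM * series$nominal_volume_mL / cp0
}

#' Marker-based volume trace
#'
#' Reconstructs the perfusate volume at each sampling instant from the
#' marker concentrations, crediting each sampling event with the withdrawn
#' volume `s` and the marker re-added with the replacement stock (`s C'`):
#'
#' * `variant = "recursive"` (default):
#'   `V_t = ((V_{t-1} - s) C'_{t-1} + s C') / C'_t` — the running
#'   numerator is exactly the marker amount assumed present after all prior
#'   withdrawals and replacements, so the assumed marker budget is conserved
#'   step by step.
#' * `variant = "literal"`: `V_t = ((V_0 - s) C'_{t-1} + s C') / C'_t` —
#'   the classical printed form, which reuses V_0 at every step and thereby
#'   double-counts volume already withdrawn in earlier samples. Kept for
#'   comparison; identical to the recursive form at t = 1 and under zero
#'   water flux.
#'
#' @param series a [perfusion_series()].
#' @param variant `"recursive"` or `"literal"`.
#' @param v0_sanity_factor warn if V_0 exceeds this multiple of V' (marker
#'   loss or assay error inflates V_0); default 1.5.
#' @return an object of class `volume_trace`: `v0_mL`, `volumes_mL` (V_t at
#'   t_1..t_n), `times_min`, `variant`.
#' @export
volume_trace <- function(series, variant = c("recursive", "literal"),
                         v0_sanity_factor = 1.5) {
  stopifnot(inherits(series, "perfusion_series"))
  variant <- match.arg(variant)
  v0 <- initial_volume(series)
  if (v0 > v0_sanity_factor * series$nominal_volume_mL) {
    warning(sprintf("V_0 = %.3g mL exceeds %.2g x nominal volume", v0,
                    v0_sanity_factor), call. = FALSE)
  }
  cp <- series$marker_concentrations_uM
  s <- series$sample_volume_mL
  cprime <- series$nominal_marker_concentration_uM
  n <- length(cp) - 1
  volumes <- numeric(n)
  v_prev <- v0
  for (t in seq_len(n)) {
    if (cp[t + 1] <= 0) {
      stop(sprintf("marker concentration at t index %d is not positive", t),
           call. = FALSE)
    }
    base <- if (variant == "recursive") v_prev else v0
    volumes[t] <- ((base - s) * cp[t] + s * cprime) / cp[t + 1]
    v_prev <- volumes[t]
  }
  structure(
    list(v0_mL = v0, volumes_mL = volumes,
         times_min = series$times_min[-1], variant = variant),
    class = "volume_trace"
  )
}

#' Volume-corrected drug concentrations
#'
#' `C_t = C_e V_t / V_0`: rescales each measured drug concentration by the
#' contemporaneous volume so that concentration changes caused purely by
#' water absorption cancel, leaving the decline attributable to drug
#' absorption.
#'
#' @param series a [perfusion_series()].
#' @param trace a [volume_trace()] aligned with the drug time points.
#' @return corrected concentrations C_t (uM) at t_1..t_n.
#' @export
corrected_concentrations <- function(series, trace) {
  stopifnot(inherits(series, "perfusion_series"),
            inherits(trace, "volume_trace"))
  if (length(trace$volumes_mL) != length(series$drug_concentrations_uM)) {
    stop("volume trace and drug series are not aligned", call. = FALSE)
  }
  series$drug_concentrations_uM * trace$volumes_mL / trace$v0_mL
}

#' First-order absorption rate from corrected concentrations
#'
#' Fits `C_t = C_0 exp(-ka t)` by ordinary least squares on the log scale:
#' `ka` is minus the slope of `ln C_t` versus `t`. Nonpositive corrected
#' concentrations cannot be log-transformed and are excluded with a warning.
#'
#' @param times_min drug sampling times (min).
#' @param concentrations_uM corrected concentrations C_t at those times.
#' @param window optional `c(min, max)` time window (minutes, inclusive)
#'   restricting the fit.
#' @return an object of class `ka_fit`: `ka_per_min`, `c0_fit_uM`
#'   (exponential of the intercept), `r_squared` (log scale),
#'   `n_points_used`.
#' @examples
#' t <- seq(10, 60, by = 10)
#' fit_ka(t, 100 * exp(-0.01 * t))$ka_per_min # 0.01
#' @export
fit_ka <- function(times_min, concentrations_uM, window = NULL) {
  if (length(times_min) != length(concentrations_uM)) {
    stop("times and concentrations must have equal length", call. = FALSE)
  }
  keep <- rep(TRUE, length(times_min))
  if (!is.null(window)) {
    keep <- times_min >= window[1] & times_min <= window[2]
  }
  pos <- concentrations_uM > 0
  if (any(keep & !pos)) {
    warning(sprintf("%d nonpositive corrected concentration(s) excluded from the ka fit",
                    sum(keep & !pos)), call. = FALSE)
  }
  keep <- keep & pos
  if (sum(keep) < 3) {
    stop("fit_ka needs at least 3 positive concentrations in the window",
         call. = FALSE)
  }
  t <- times_min[keep]
  y <- log(concentrations_uM[keep])
  fit <- ols_fit(t, y)
  structure(
    list(ka_per_min = -fit$slope, c0_fit_uM = exp(fit$intercept),
         r_squared = fit$r_squared, n_points_used = sum(keep)),
    class = "ka_fit"
  )
}

#' Effective permeability from the absorption rate
#'
#' `Peff = ka R / 2` for a cylindrical lumen of radius R, with `ka`
#' converted from 1/min to 1/s.
#'
#' @param fit a [fit_ka()] result, or a plain ka value in 1/min.
#' @param geometry a [segment_geometry()].
#' @return Peff in cm/s.
#' @export
peff_from_ka <- function(fit, geometry) {
  stopifnot(inherits(geometry, "segment_geometry"))
  ka <- if (inherits(fit, "ka_fit")) fit$ka_per_min else fit
  rate_to_permeability(ka, geometry$radius_cm)
}

#' Water flux from the volume trace
#'
#' The net water absorption rate per cm of intestine,
#' `Jwater = d(V_0 - V_t)/dt / L`, with the slope taken by ordinary least
#' squares over all volume points including the origin (0, 0) — a per-sample
#' regression rather than an endpoint difference, so every sampling instant
#' informs the estimate. The endpoint alternative
#' `(V_0 - V_n) / t_n / L`, which depends only on the final sample, is
#' returned alongside for comparison. Both are reported in uL/cm/h.
#'
#' @param trace a [volume_trace()].
#' @param times_min sampling times of the trace volumes; defaults to the
#'   times stored in the trace.
#' @param geometry a [segment_geometry()].
#' @return an object of class `water_flux`: `jwater_uL_per_cm_per_h`
#'   (regression), `r_squared`, `jwater_endpoint_uL_per_cm_per_h`,
#'   `slope_mL_per_min`.
#' @examples
#' g <- segment_geometry("jejunum") # L = 10 cm
#' tr <- structure(list(v0_mL = 20, volumes_mL = 20 - 0.025 * c(10, 20, 30),
#'                      times_min = c(10, 20, 30), variant = "recursive"),
#'                 class = "volume_trace")
#' water_flux(tr, geometry = g)$jwater_uL_per_cm_per_h # 150
#' @export
water_flux <- function(trace, times_min = NULL, geometry) {
  stopifnot(inherits(trace, "volume_trace"),
            inherits(geometry, "segment_geometry"))
  if (is.null(times_min)) times_min <- trace$times_min
  if (length(times_min) != length(trace$volumes_mL)) {
    stop("times and trace volumes must have equal length", call. = FALSE)
  }
  if (length(times_min) < 3) {
    stop("water_flux needs at least 3 volume points", call. = FALSE)
  }
  t <- c(0, times_min)
  y <- c(0, trace$v0_mL - trace$volumes_mL)
  fit <- ols_fit(t, y)
  slope <- fit$slope # mL/min of whole-segment volume loss
  n <- length(y)
  endpoint <- (y[n] / t[n])
  structure(
    list(jwater_uL_per_cm_per_h = rate_to_jwater(slope, geometry$length_cm),
         r_squared = fit$r_squared,
         jwater_endpoint_uL_per_cm_per_h = rate_to_jwater(endpoint,
                                                          geometry$length_cm),
         slope_mL_per_min = slope),
    class = "water_flux"
  )
}

#' Full perfusion analysis chain
#'
#' Runs the complete correction and estimation chain on one perfusion time
#' series: initial volume, marker-based volume trace, corrected drug
#' concentrations, log-linear ka fit, `Peff = ka R / 2`, and the
#' regression-based water flux.
#'
#' @param series a [perfusion_series()].
#' @param variant volume-trace variant, see [volume_trace()].
#' @param window optional time window (minutes) for the ka fit.
#' @return an object of class `perfusion_result`: `peff_cm_per_s`,
#'   `ka_fit`, `jwater` (a `water_flux` object), `volume_trace`,
#'   `corrected_concentrations_uM`.
#' @examples
#' run <- simulate_perfusion_run(
#'   segment_geometry("jejunum"), perfusion_design(),
#'   solute_spec("PEG5k-PR-like", "marker", 3e-7, 56),
#'   solute_spec("metoprolol-like", "drug", 1e-4, 100))
#' analyze_perfusion(run$observations)
#' @export
analyze_perfusion <- function(series, variant = c("recursive", "literal"),
                              window = NULL) {
  stopifnot(inherits(series, "perfusion_series"))
  variant <- match.arg(variant)
  trace <- volume_trace(series, variant)
  ct <- corrected_concentrations(series, trace)
  fit <- fit_ka(series$times_min[-1], ct, window = window)
  structure(
    list(peff_cm_per_s = peff_from_ka(fit, series$geometry),
         ka_fit = fit,
         jwater = water_flux(trace, geometry = series$geometry),
         volume_trace = trace,
         corrected_concentrations_uM = ct),
    class = "perfusion_result"
  )
}

#' @export
print.perfusion_result <- function(x, ...) {
  cat(sprintf(paste0("<perfusion_result>\n",
                     "  Peff   = %.4g cm/s (ka = %.4g /min, r^2 = %.4f, n = %d)\n",
                     "  Jwater = %.4g uL/cm/h (r^2 = %.4f; endpoint %.4g)\n",
                     "  V_0    = %.4g mL (%s volume trace)\n"),
              x$peff_cm_per_s, x$ka_fit$ka_per_min, x$ka_fit$r_squared,
              x$ka_fit$n_points_used, x$jwater$jwater_uL_per_cm_per_h,
              x$jwater$r_squared, x$jwater$jwater_endpoint_uL_per_cm_per_h,
              x$volume_trace$v0_mL, x$volume_trace$variant))
  invisible(x)
}
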