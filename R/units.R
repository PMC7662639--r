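#' Unit conversions
#'
#' The package fixes one internal unit system: concentrations uM, volumes mL,
#' times min, permeabilities cm/s, water flux uL/cm/h. Amounts are therefore
#' nmol (uM x mL). These helpers convert between the reporting units and the
#' per-minute rates used by the simulator and the fitting code.
#'
#' For a cylindrical lumen of radius `R` the first-order luminal disappearance
#' rate implied by a membrane permeability `P` is `ka = 2 P / R` (per second):
#' the exposed surface per lumen volume of a cylinder is `2/R`. This is the
#' exact inverse of the conversion `Peff = ka * R / 2` used when reporting
#' permeabilities, so simulated and estimated permeabilities live on the same
#' operational scale.
#'
#' @param p_cm_per_s permeability in cm/s.
#' @param radius_cm effective lumen radius in cm.
#' @param ka_per_min first-order disappearance rate in 1/min.
#' @param jwater_uL_per_cm_per_h net water absorption per cm of intestine per
#'   hour.
#' @param length_cm perfused length in cm.
#' @param q_mL_per_min volume loss rate of the whole segment in mL/min.
#' @return the converted quantity (numeric scalar or vector).
#' @examples
#' permeability_to_rate(2.5e-5, radius_cm = 0.18) # atenolol-like ka, 1/min
#' jwater_to_rate(150, length_cm = 10)            # 0.025 mL/min
#' @name units
NULL

#' @rdname units
#' @export
permeability_to_rate <- function(p_cm_per_s, radius_cm) {
  stopifnot(radius_cm > 0)
  2 * p_cm_per_s / radius_cm * 60
}

#' @rdname units
#' @export
rate_to_permeability <- function(ka_per_min, radius_cm) {
  stopifnot(radius_cm > 0)
  ka_per_min / 60 * radius_cm / 2
}

#' @rdname units
#' @export
jwater_to_rate <- function(jwater_uL_per_cm_per_h, length_cm) {
  stopifnot(length_cm > 0)
  jwater_uL_per_cm_per_h * length_cm / 1000 / 60
}

#' @rdname units
#' @export
rate_to_jwater <- function(q_mL_per_min, length_cm) {
  stopifnot(length_cm > 0)
  q_mL_per_min * 1000 * 60 / length_cm
}

#' Membrane surface area of a segment
#'
#' Smooth-cylinder area `A = 2 pi R L`, optionally scaled by a multiplier to
#' represent mucosal amplification (villi etc.), which the smooth-cylinder
#' convention ignores.
#'
#' @param geometry a [segment_geometry()].
#' @param multiplier dimensionless area multiplier, default 1.
#' @return area in cm^2.
#' @export
surface_area <- function(geometry, multiplier = 1) {
  stopifnot(inherits(geometry, "segment_geometry"), multiplier > 0)
  2 * pi * geometry$radius_cm * geometry$length_cm * multiplier
}

# OLS slope/intercept/r^2 without summary.lm (which warns on perfect fits).
# With zero total variation the fit is trivially exact: r^2 = 1.
ols_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
  co <- stats::coef(fit)
  list(intercept = unname(co[1]), slope = unname(co[2]),
       r_squared = min(max(r2, 0), 1))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed deterministically; kept under 2^31-1.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %%
               2147483647)
}
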