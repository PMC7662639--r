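#' Study descriptor for cohort generation
#'
#' Bundles everything needed to simulate one animal's experiment: the
#' experiment type, geometry, design and solute specifications. Per-animal
#' parameters (water flux, permeabilities) are redrawn around these scenario
#' means by [generate_cohort()].
#'
#' @param type `"perfusion"` or `"egs"`.
#' @param geometry a [segment_geometry()].
#' @param design a [perfusion_design()] or [egs_design()] matching `type`.
#' @param marker,drug perfusion solutes ([solute_spec()]).
#' @param solute EGS solute ([solute_spec()]).
#' @return an object of class `study_descriptor`.
#' @export
study_descriptor <- function(type = c("perfusion", "egs"), geometry, design,
                             marker = NULL, drug = NULL, solute = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(geometry, "segment_geometry"))
  if (type == "perfusion") {
    stopifnot(inherits(design, "perfusion_design"),
              inherits(marker, "solute_spec"), inherits(drug, "solute_spec"))
  } else {
    stopifnot(inherits(design, "egs_design"), inherits(solute, "solute_spec"))
  }
  structure(list(type = type, geometry = geometry, design = design,
                 marker = marker, drug = drug, solute = solute),
            class = "study_descriptor")
}

#' Generate a cohort of simulated animals
#'
#' Draws per-animal true parameters lognormally around the scenario means
#' (water flux with CV `animal_cv_jwater`, every permeability with CV
#' `animal_cv_permeability`) and simulates one run per animal. Each run gets
#' an independent assay-noise stream derived deterministically from the base
#' seed, so a cohort is a pure function of (descriptor, noise model).
#'
#' @param study a [study_descriptor()].
#' @param n_animals number of animals, >= 2.
#' @param noise a [noise_model()]; its `seed` drives both the parameter draws
#'   and the per-run assay noise.
#' @param run_prefix prefix for run identifiers (`<prefix>1`, `<prefix>2`, ...).
#' @return list of `simulated_run` objects, one per animal.
#' @examples
#' st <- study_descriptor("perfusion", segment_geometry("jejunum"),
#'   perfusion_design(),
#'   marker = solute_spec("PEG5k-PR-like", "marker", 3e-7, 56),
#'   drug = solute_spec("atenolol-like", "drug", 2.5e-5, 100))
#' cohort <- generate_cohort(st, 6, noise_model(0.05, 0.4, 0.3, seed = 11))
#' sapply(cohort, function(r) r$truth$jwater_uL_per_cm_per_h)
#' @export
generate_cohort <- function(study, n_animals, noise = noise_model(),
                            run_prefix = "run") {
  stopifnot(inherits(study, "study_descriptor"), inherits(noise, "noise_model"))
  if (!is.numeric(n_animals) || n_animals < 2 || n_animals != round(n_animals)) {
    stop("n_animals must be an integer >= 2", call. = FALSE)
  }
  n_animals <- as.integer(n_animals)

  draws <- with_preserved_rng(noise$seed, {
    if (study$type == "perfusion") {
      list(
        jwater = rlnorm_mean_cv(n_animals,
                                study$design$true_jwater_uL_per_cm_per_h,
                                noise$animal_cv_jwater),
        marker_p = rlnorm_mean_cv(n_animals,
                                  study$marker$permeability_cm_per_s,
                                  noise$animal_cv_permeability),
        drug_p = rlnorm_mean_cv(n_animals, study$drug$permeability_cm_per_s,
                                noise$animal_cv_permeability)
      )
    } else {
      list(
        solute_p = rlnorm_mean_cv(n_animals,
                                  study$solute$permeability_cm_per_s,
                                  noise$animal_cv_permeability)
      )
    }
  })

  lapply(seq_len(n_animals), function(i) {
    run_noise <- noise_model(assay_cv = noise$assay_cv,
                             seed = derive_seed(noise$seed, i))
    id <- paste0(run_prefix, i)
    if (study$type == "perfusion") {
      design_i <- study$design
      design_i$true_jwater_uL_per_cm_per_h <- draws$jwater[i]
      marker_i <- study$marker
      marker_i$permeability_cm_per_s <- draws$marker_p[i]
      drug_i <- study$drug
      drug_i$permeability_cm_per_s <- draws$drug_p[i]
      simulate_perfusion_run(study$geometry, design_i, marker_i, drug_i,
                             run_noise, run_id = id)
    } else {
      solute_i <- study$solute
      solute_i$permeability_cm_per_s <- draws$solute_p[i]
      simulate_egs_run(study$geometry, study$design, solute_i, run_noise,
                       run_id = id)
    }
  })
}
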