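# Default comparative-study scenario for perfusim.
#
# Permeabilities are in cm/s, concentrations in uM, volumes in mL, times in
# minutes, water flux in uL/cm/h. The marker and drug values are
# literature-typical rat values: a classical phenol-red-like marker around
# 5e-6 cm/s against PEGylated markers 6-15-fold less permeable, with the
# segmental trend jejunum > duodenum > ileum > colon; drug permeabilities
# span the BCS range, from a low-permeability paracellular drug (~2.5e-5)
# to high-permeability drugs (~1e-4). These numbers parameterize the
# simulation scenarios; they are inputs, not results.

markers:
  PR-like:
    concentration_uM: 56
    papp_cm_per_s: {duodenum: 4.5e-6, jejunum: 5.0e-6, ileum: 3.5e-6, colon: 2.5e-6}
  PEG4k-PR-like:
    concentration_uM: 56
    papp_cm_per_s: {duodenum: 7.2e-7, jejunum: 8.0e-7, ileum: 5.6e-7, colon: 4.0e-7}
  PEG5k-PR-like:
    concentration_uM: 56
    papp_cm_per_s: {duodenum: 2.7e-7, jejunum: 3.0e-7, ileum: 2.1e-7, colon: 1.5e-7}

drugs:
  atenolol-like:       # BCS III, low permeability, paracellular
    concentration_uM: 100
    peff_cm_per_s: {duodenum: 2.5e-5, jejunum: 2.6e-5, ileum: 2.3e-5, colon: 3.3e-5}
  ketoprofen-like:     # BCS II
    concentration_uM: 100
    peff_cm_per_s: {duodenum: 1.0e-4, jejunum: 1.0e-4, ileum: 1.11e-4, colon: 1.29e-4}
  metoprolol-like:     # BCS I, high-permeability reference
    concentration_uM: 100
    peff_cm_per_s: {duodenum: 1.0e-4, jejunum: 1.07e-4, ileum: 9.4e-5, colon: 1.02e-4}

segments: [duodenum, jejunum, ileum, colon]
n_animals_per_group: 6
true_jwater_uL_per_cm_per_h: 200
jwater_segment: jejunum
reference_marker: PR-like
geometry_radius_cm: 0.18

# recirculation protocol: 20 mL circuit, 0.4-mL samples every 10 min for
# 60 min after a 10-min stabilization; withdrawn volume replaced with
# marker stock (no drug re-addition)
perfusion:
  nominal_volume_mL: 20
  sample_volume_mL: 0.4
  sampling_interval_min: 10
  n_samples: 6
  replacement_policy: marker_stock
  stabilization_min: 10
  t0_marker_in_replacement: true

noise:
  assay_cv: 0.05              # multiplicative HPLC-like measurement noise
  animal_cv_jwater: 0.4       # lognormal inter-animal CV of water flux
  animal_cv_permeability: 0.3 # lognormal inter-animal CV of permeabilities
  seed: 1

analysis:
  variant: recursive   # volume trace conserves the assumed marker amount
  window: null         # ka fit over all drug time points
  var_equal: false     # Welch t-test
  holm: false          # no multiplicity adjustment across comparisons
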