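# perfusim

Water-flux correction and permeability estimation for rat in situ
recirculation perfusion and everted gut sac (EGS) experiments — plus a
mass-balance simulator with known ground truth, so the whole estimation
chain can be validated by parameter recovery.

## The problem

In situ recirculation perfusion estimates a drug's effective intestinal
membrane permeability (*P*<sub>eff</sub>) from its first-order disappearance
in the recirculating perfusate. Water absorption shrinks the perfusate and
concentrates everything in it, so a "nonabsorbable" volume marker is
co-perfused and the measured drug concentrations are corrected for the
reconstructed volume. Classical markers (phenol red) are themselves
measurably absorbed; a self-absorbing marker inflates the reconstructed
volumes and biases both the net water flux (*J*<sub>water</sub>) and
*P*<sub>eff</sub> downward — most severely for poorly permeable (BCS III)
drugs. perfusim implements the correction chain, simulates the bias
mechanism, and quantifies it.

The estimation chain, for marker concentrations *C′*<sub>t</sub>, drug
concentrations *C*<sub>e</sub>, nominal marker concentration *C′*, nominal
volume *V′* and sample volume *s*:

- initial volume: *V*<sub>0</sub> = *C′V′* / *C′*<sub>0</sub>
- volume trace (marker-amount conserving):
  *V*<sub>t</sub> = ((*V*<sub>t−1</sub> − *s*) *C′*<sub>t−1</sub> + *s C′*) / *C′*<sub>t</sub>
- corrected concentration: *C*<sub>t</sub> = *C*<sub>e</sub> *V*<sub>t</sub> / *V*<sub>0</sub>
- absorption rate: *C*<sub>t</sub> = *C*<sub>0</sub> e<sup>−ka·t</sup> (log-linear OLS)
- permeability: *P*<sub>eff</sub> = *k*<sub>a</sub> *R* / 2
- water flux: *J*<sub>water</sub> = OLS slope of (*V*<sub>0</sub> − *V*<sub>t</sub>) vs *t*, per cm of intestine

and for the EGS assay: *Q*<sub>n</sub> = *C*<sub>n</sub>*V* + *s* Σ *C*<sub>i</sub>,
*P*<sub>app</sub> = (d*Q*/d*t*)/(*A C*<sub>0</sub>), *W* = *Q*<sub>n</sub>/(*V*<sub>ref</sub> *C*<sub>0</sub>).

See the methods vignette (`vignettes/water-flux-correction.Rmd`) for the
model, the design decisions and the quantified residual biases.

## Worked example

Simulate one jejunal perfusion (true *J*<sub>water</sub> = 200 uL/cm/h,
atenolol-like drug with true *P*<sub>eff</sub> = 2.5e-5 cm/s) under a
phenol-red-like marker (Papp 5e-6 cm/s), then analyze it:

```r
library(perfusim)
run <- simulate_perfusion_run(
  segment_geometry("jejunum"),
  perfusion_design(true_jwater_uL_per_cm_per_h = 200),
  marker = solute_spec("PR-like", "marker", 5e-6, 56),
  drug   = solute_spec("atenolol-like", "drug", 2.5e-5, 100)
)
analyze_perfusion(run$observations)
#> <perfusion_result>
#>   Peff   = 2.328e-05 cm/s (ka = 0.01552 /min, r^2 = 1.0000, n = 6)
#>   Jwater = -195.7 uL/cm/h (r^2 = 0.9999; endpoint -195.5)
#>   V_0    = 20.33 mL (recursive volume trace)
```

The marker's own absorption outpaces the water-flux concentration rise, so
the reconstructed volume *grows*: the estimated water flux comes out
strongly negative (truth: +200) and *P*<sub>eff</sub> is biased low.
The same run under a PEGylated low-permeability marker (Papp 3e-7 cm/s):

```r
#> <perfusion_result>
#>   Peff   = 2.795e-05 cm/s (ka = 0.01863 /min, r^2 = 1.0000, n = 6)
#>   Jwater = 178.9 uL/cm/h (r^2 = 1.0000; endpoint 178.9)
#>   V_0    = 19.71 mL (recursive volume trace)
```

Jwater is now near truth; the remaining +12% on *P*<sub>eff</sub> is the
documented sampling-dilution offset of the 0.4-mL/10-min design (see the
vignette), which vanishes as the sample volume does.

The comparative study (6 simulated animals per marker group, identical true
water flux, inter-animal and assay noise on):

```r
cfg <- default_study_config(seed = 1)
jw <- run_marker_comparison(cfg)
jw$summary
#>          marker segment mean_jwater sd_jwater n true_jwater
#> 1       PR-like jejunum      -121.6    195.21 6         200
#> 2 PEG4k-PR-like jejunum       195.2     94.43 6         200
#> 3 PEG5k-PR-like jejunum       161.6     69.83 6         200
jw$comparisons[, c("group_b", "mean_a", "mean_b", "t_p")]
#>         group_b mean_a mean_b      t_p
#> 1 PEG4k-PR-like -121.6  195.2 0.008544
#> 2 PEG5k-PR-like -121.6  161.6 0.014562
```

Both PEGylated-marker groups recover water fluxes near the truth and differ
significantly (Welch p < 0.05) from the classical-marker group, whose mean
is driven negative. `run_peff_study()` runs the analogous drug x segment x
marker factorial for *P*<sub>eff</sub>.

## Command line

```sh
Rscript inst/cli/perfusim.R study --out results_dir --seed 42
Rscript inst/cli/perfusim.R simulate-perfusion --out sim --n 6 --seed 7
Rscript inst/cli/perfusim.R analyze-perfusion --observations sim/observations.csv --out ana
```

Subcommands: `simulate-perfusion`, `simulate-egs`, `analyze-perfusion`,
`analyze-egs`, `study`. Configuration is YAML (commented example:
`inst/extdata/default_study.yaml`); observation tables are tidy CSV
(`run_id, experiment_type, segment, time_min, analyte, concentration_uM`).
Rerunning any subcommand with the same seed and config reproduces its
result files byte for byte.

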