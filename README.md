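# rbcassay

Simulation and analysis of the laboratory assays used to quantify
drug-induced damage to red blood cells (RBCs): laser-diffraction osmotic
fragility, microfluidic single-cell transit velocimetry,
spectrophotometric hemoglobin quantification, hematology/flow-cytometry
summaries, and the accompanying group statistics. The package is aimed
at hematology and biophysics labs analysing these measurements and at
method developers who need a fully synthetic, ground-truthed test bed
for the estimators.

## What it computes

**Osmotic fragility (OFT).** As medium osmolality is lowered from
isotonic (300 mOsmol) toward 100 mOsmol, cells swell as van't Hoff
osmometers, `V(c) = Vs + (V300 − Vs)·300/c`, then lyse at a per-cell
threshold. From a multi-angle scattered-light recording the package
computes the hemolysis curve, the osmolalities of 50/10/90% lysis (H50,
H10, H90), the heterogeneity width `W = |H10 − H90|`, the hydrodynamic
volume curve `MCV_osm(c) = MCV300 · (per-cell SLI ratio)^(3/2)`, and the
asphericity index `AI = 100·2√2·SD/mean` of the isotonic SLI
oscillations (zero for spheres, large for discocytes).

**Microfluidic transit.** Cells are tracked through microchannel image
stacks (threshold detection, nearest-neighbor linking, Theil–Sen
velocity fits), velocities are normalized to the wide-channel bulk flow
(a.u., 1 = moving with the flow), per-experiment probability densities
are averaged with SE bands, and the slow-cell fraction below the
0.175 a.u. cutoff, the mirrored fast fraction and the channel occlusion
rate are reported. The cutoff can also be re-derived from a control
distribution as the quantile at a stated tail mass.

**Hemoglobin spectrophotometry.** Free hemoglobin as the
turbidity-corrected 540 nm supernatant absorbance relative to the whole
lysate (100%), and oxyHb/metHb/hemichrome fractions by nonnegative
least-squares unmixing of 560/577/630 nm absorbances against a
configurable extinction matrix (700 nm as turbidity baseline).

**Hematology & cytometry.** MCV, RDW% (CV of volume) and RDW-SD (width
of the volume histogram at 20% of peak height, → 3.588·σ for Gaussian
volumes); MFI as percent of control with negative-control subtraction;
positivity gating against an unstained control; microparticle gating on
forward scatter.

**Statistics & dosing.** D'Agostino–Pearson normality screening, then
one-way ANOVA + Tukey HSD or Kruskal–Wallis + Dunn versus control with
figure-legend significance tiers; per-BSA dose to blood/suspension
concentration conversion and the suspension hematocrit check.

Every assay has a matching synthetic generator (`sample_population()`,
`simulate_oft_recording()`, `simulate_velocity_dataset()`,
`render_microchannel_frames()`, `simulate_absorbance()`,
`simulate_cytometry_events()`), so the full pipeline runs and is tested
without any external data.

## Worked example

Recover an osmotic-fragility shift between a control population and a
treated one whose lysis thresholds are 6.4 mOsmol lower:

```r
library(rbcassay)

ctrl <- population_spec(n_cells = 5000, seed = 1)
trt  <- population_spec(n_cells = 5000,
                        lysis_osm = list(mean = 135.6, sd = 8), seed = 2)

rec_c <- simulate_oft_recording(sample_population(ctrl),
                                noise_sd = 0.01, seed = 3)
rec_t <- simulate_oft_recording(sample_population(trt),
                                noise_sd = 0.01, seed = 4)

rs_c <- resistance_summary(lysed_fraction_curve(rec_c))
rs_t <- resistance_summary(lysed_fraction_curve(rec_t))
sprintf("control H50 %.1f, treated H50 %.1f, shift %.2f mOsmol",
        rs_c$h50, rs_t$h50, rs_c$h50 - rs_t$h50)
#> "control H50 142.2, treated H50 135.4, shift 6.75 mOsmol"

head(mcv_osm_curve(rec_c, mcv_300 = 90), 4)
#>   osmolality mcv_fl
#> 1        300  90.00
#> 2        290  91.36
#> 3        280  92.75
#> 4        270  94.55
```

The shift estimate (6.75 mOsmol at these two seeds) recovers the
generating 6.4 mOsmol difference to within the grid-interpolation and
sampling error; the volume curve starts exactly at the supplied
reference MCV and rises as the cells swell. A slow-cell mixture is
recovered the same way:

```r
spec <- population_spec(n_cells = 20000, velocity = list(
  main = list(weight = 0.911, mean = 1.0, sd = 0.15, lower = 0, upper = Inf),
  slow = list(weight = 0.089, mean = 0.10, sd = 0.03, lower = 0, upper = 0.175),
  fast = list(weight = 0, mean = 1.6, sd = 0.1)), seed = 5)
slow_fast_fractions(simulate_velocity_dataset(spec))$slow_fraction
#> [1] 9.025
```

An end-to-end run over several treatment groups — synthetic generation,
OFT, microfluidics, hematology, statistics, CSV/JSON/plot outputs — is
driven by one YAML config via `run_pipeline()`; see `?run_pipeline`.

## Methods

The model assumptions, estimator definitions, numerical conventions and
known limitations are documented in the methods vignette,
`vignettes/rbc-damage-assays.Rmd`.
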