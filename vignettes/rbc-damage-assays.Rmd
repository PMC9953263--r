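---
title: "Quantifying red-cell damage: models and methods in rbcassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying red-cell damage: models and methods in rbcassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcassay)
```

# The measurement problem

Chemotherapy drugs damage circulating red blood cells (RBCs) long before
frank anemia appears. The damage is heterogeneous — a treated sample is
usually a mixture of near-normal cells and a small, badly affected
subpopulation — so the informative readouts are whole-distribution
measurements rather than single means: the osmotic fragility curve, the
distribution of single-cell transit velocities through capillary-sized
microchannels, the volume histogram, and the spectrum of hemoglobin
released or oxidized. `rbcassay` implements those analyses together with
a synthetic-data generator that produces raw measurements with the same
statistical structure, so that every estimator in the package can be
validated against a known ground truth.

# The synthetic cell population

Each simulated cell carries an isotonic volume $V_{300}$ (fL), an
osmotically inactive ("nonsolvent") volume $V_s$ (fL), a lysis threshold
(mOsmol), an oblate axis ratio $q \in (0, 1]$ (1 = sphere, small $q$ =
flattened discocyte), a normalized transit-velocity factor, an adhesion
propensity, an esterase activity and a phosphatidylserine flag. Fields
are drawn independently from per-group mean/SD settings
(`population_spec()`); the transit velocity comes from a declared
mixture of a main component near 1 a.u. and optional slow/fast tails.

Control defaults — $V_{300} = 90 \pm 5$ fL, $V_s$ about 55% of the
isotonic volume, lysis threshold $142 \pm 8$ mOsmol, $q = 0.30 \pm
0.03$, a single velocity component at $1.0 \pm 0.15$ a.u., zero
adhesion — describe a healthy donor population with typical hematology
values; treated groups are expressed as deviations from these (a shifted
lysis mean, a reduced $1-q$ amplitude, a slow-tail weight, a nonzero
adhesion propensity). The absolute control lysis threshold is a
configurable convention, not a measured constant: fragility analyses in
this package are interpreted through *differences* between groups, which
is also how the assays are used in practice.

What the generator deliberately does **not** emulate: rigorous
small-angle (Mie/anomalous-diffraction) scattering, cell deformation
inside channels, camera noise beyond additive Gaussian, and optical
crosstalk between detection angles. Passing tests therefore demonstrate
that the estimators recover the parameters of this idealized measurement
process, not that they are unbiased on any particular instrument.

# Osmotic fragility from scattered light

## Swelling and lysis model

An intact cell at osmolality $c$ has the van't Hoff osmometer volume

$$V(c) = V_s + (V_{300} - V_s)\,\frac{300}{c},$$

and lyses instantaneously when $c$ falls to its threshold. With the
printed pair $V(300) = 84.6$ fL and $V(200) = 91.6$ fL this two-parameter
law solves to $V_s = 70.6$ fL; that arithmetic is the oracle behind the
volume-recovery tests.

## The scattered-light record

The recording steps through plateaus from 300 down to 100 mOsmol
(default spacing 10 mOsmol, 20 s and 200 samples per plateau at 10 Hz —
sizes chosen so a full recording of 5,000 cells simulates in well under
a second while leaving 200 isotonic samples for the oscillation
statistic). At each sample the signal at angle $a$ is a sum over intact
cells of a projected-area term times an orientation factor:

* angles $\le 6°$: term $\propto V(c)^{2/3}$ — swelling raises the
  signal;
* angles $> 6°$: term fixed at $V_{300}^{2/3}$ — insensitive to
  swelling;
* all angles: proportional to the number of intact cells, so hemolysis
  lowers every channel.

This angle asymmetry is a deliberate modeling choice: with it, a
low-angle channel (default 2.5°) and a high-angle channel (default 12°)
jointly identify both the per-cell swelling factor and the intact
fraction. If every angle carried the same volume dependence, no
combination of channels could separate "cells swelling" from "cells
disappearing", and the volume-corrected hemolysis estimator below would
be unidentifiable.

The orientation factor is $1 + (1 - q)\,u$ with one $u$ per time sample
shared across cells, drawn as a randomly permuted stratified grid on
$[-1, 1]$. The stratification expresses that over a 20 s plateau the
rotation phase covers orientation space uniformly; it makes the
plateau-mean orientation factor exactly one (so orientation noise never
leaks into the plateau means used by the curve estimators) while keeping
the sample-to-sample oscillation amplitude at its analytic value:
peak-to-peak relative amplitude $2(1-q)$, zero for spheres.

## Estimators

**Hemolysis curve.** With $r_a(c)$ the plateau-mean SLI at angle $a$
normalized to its 300 mOsmol value, the swelling factor per intact cell
is $s(c) = r_{2.5}(c) / r_{12}(c)$ and the lysed fraction at the default
6° hemolysis angle is $1 - r_6(c)/s(c)$, clamped to $[0,1]$. When the
chosen hemolysis angle is itself above 6° the correction is not needed
and the lysed fraction is simply $1 - r_a(c)$. The curve is made
monotone by pool-adjacent-violators regularization before any threshold
is read; on noiseless recordings it matches the generator's bookkeeping
to well under one percentage point.

**H50, H10, H90, W.** Thresholds are located by linear interpolation
between the two bracketing plateaus — matching the stepwise acquisition
— and an error names any threshold the curve never crosses. The
heterogeneity width is reported as the nonnegative span
$W = |H10 - H90|$; the two H-values themselves make the sign convention
unambiguous. With 10 mOsmol plateaus and a Normal(142, 8) threshold
distribution the interpolation bias of a single H50 is about
0.2–0.3 mOsmol; group *differences* cancel most of it, which the
recovery tests confirm (bias < 0.5 mOsmol, SD < 1 mOsmol over 20 seeds
at n = 5,000 and 1% noise).

**MCV\_osm.** The per-intact-cell low-angle signal is
$r_{2.5}(c)/r_{12}(c)$; the projected-area convention
SLI $\propto V^{2/3}$ inverts to

$$\mathrm{MCV}_{osm}(c) = \mathrm{MCV}_{300}\,
  \left(\frac{r_{2.5}(c)}{r_{12}(c)}\right)^{3/2},$$

anchored exactly to the hematology-analyser MCV at 300 mOsmol. The
$V^{2/3}$ area-to-volume convention is a documented package choice,
validated against the generator (instrument software may use a different
internal calibration).

**Asphericity index.** On the isotonic plateau (at least 200 samples,
default angle 2.5°) the trace is linearly detrended and

$$\mathrm{AI} = 100 \cdot \frac{2\sqrt{2}\,\mathrm{SD}}{\mathrm{mean}},$$

which equals peak-to-peak over mean for a sinusoid and is stable in the
number of samples. Flattened cells give large AI, spheres give zero; a
population generated with one third of the control amplitude returns an
AI ratio of 3 within sampling error.

# Microfluidic transit analysis

## Tracking

`track_cells()` detects cells as connected components darker than a
threshold (default: background estimated as the stack median, minus a
quarter of the background-to-minimum range), gates them by area
(≥ 5 px), and takes darkness-weighted centroids. Linking is
nearest-neighbor with a per-frame displacement gate (default 15 px),
shortest displacement first, ties broken by lowest track id. Frames are
0-based and pixel centers sit at integer coordinates — the same
convention the renderer uses for its ground-truth table, so tracker and
truth can be compared cell by cell. Per-track velocity is the Theil–Sen
(median-of-pairwise-slopes) fit of x against frame, which shrugs off a
single mis-detection; tracks shorter than 3 frames are dropped with a
reported count. Velocities are normalized by the mean cell velocity in
wide channels (the bulk flow velocity), giving the a.u. scale on which
1 means "moving with the flow".

## Distributions, subpopulations, occlusions

Per-experiment velocity histograms are converted to densities on a
common grid (default bin width 0.025 a.u. on $[0, 2]$ — fine enough to
resolve the slow-cell cutoff region) and averaged pointwise across
experiments with an SE band, so experiments with many cells do not
dominate the averaged shape.

The slow fraction is the percentage of cells below 0.175 a.u. That
cutoff can be taken as a fixed convention or re-derived per control via
`calibrate_cutoff()`, the empirical quantile at a stated control tail
mass (default 0.45%); both modes are provided because either could be
the operative convention in practice, and the pair is mutually
consistent to within one cell by construction. The fast-cell cutoff has
no established convention, so the package mirrors the slow-tail logic
(default: 99.75th control percentile), configurable. A channel counts as
occluded when any of its cells arrests (generator truth), or — from
trajectories — when a track stays within 2 px for at least 100
consecutive frames (0.25 s at 400 fps), a quantitative stand-in for the
visual "blocked channel" call.

# Hemoglobin spectrophotometry

Free hemoglobin is the turbidity-corrected 540 nm absorbance of the
supernatant relative to the fully lysed whole-blood reference
(taken as 100%), each scaled by its dilution:
$100\,[(A_{540}-A_{700})\,d]_{sup} / [(A_{540}-A_{700})\,d]_{lys}$. The
700 nm read carries no heme absorbance and removes the flat turbidity
offset (the generator applies a constant 0.1 OD by default, precisely so
that tests exercise this correction).

Species unmixing solves Beer–Lambert
$\varepsilon c = A_{\mathrm{corr}}$ at 560/577/630 nm for
oxyhemoglobin, methemoglobin and hemichrome by nonnegative least
squares, then normalizes concentrations to fractions. NNLS rather than
the exact $3{\times}3$ solve keeps noisy spectra from returning negative
species; the two agree whenever the exact solution is nonnegative, and
that equivalence is tested. The shipped extinction matrix contains
literature-style defaults (condition number ≈ 12) and is an explicit
configuration input — laboratories should substitute their own
coefficient table. An ill-conditioned matrix (condition number $>10^6$)
and an all-zero corrected spectrum are rejected rather than fitted.

# Hematology and cytometry summaries

RDW-SD is the width of the volume histogram at 20% of its peak height.
Because that level is ill-defined on a raw noisy histogram, the volumes
are smoothed with a Gaussian kernel whose bandwidth equals the bin width
(default 1 fL) and the 20% level is crossed by linear interpolation on
both flanks; if the level is crossed more than twice the widest span is
used with a warning. For Gaussian volumes the statistic converges to
$2\sqrt{2\ln 5}\,\sigma \approx 3.588\,\sigma$ with under 1% of kernel
broadening at the default bandwidth; an exactly constant sample returns
0 (resolution floor). RDW% is the plain coefficient of variation, and
the contrast between the two (width-at-height versus CV) is the reason
both are reported.

MFI normalization uses the arithmetic mean — the literal reading of
"mean fluorescence intensity" — and subtracts an unstained negative
control from both treated and control before forming the percentage, so
drug autofluorescence cancels; the result is invariant under any affine
gain applied to all three tables. Positivity gating places the threshold
at the 99.5th percentile of the unstained control (standard practice
when no instrument gate is recorded; configurable), and the
microparticle gate counts events at or below an externally calibrated
forward-scatter bound.

# Group statistics and dosing

`compare_groups()` screens every group with the D'Agostino–Pearson
omnibus $K^2$ test; if all groups pass at $\alpha = 0.05$ the family is
compared by one-way ANOVA with Tukey HSD, otherwise — including when any
group is too small or too degenerate to test — the whole family drops to
Kruskal–Wallis with Dunn's comparisons versus control
(Bonferroni-adjusted). A single failing group switches the entire
family, reflecting a per-dataset rather than per-group test choice.
Significance tiers follow the figure-legend convention
(\*, \*\*, \*\*\*, \*\*\*\* at 0.05/0.01/0.001/0.0001).

`dose_to_concentration()` converts a per-body-surface-area dose to a
whole-blood concentration ($\mathrm{dose} \cdot S / V$, defaults
$S = 1.81\ \mathrm{m}^2$, $V = 4.5$ L) and scales it to a washed
suspension by the cell-concentration ratio (default
$5\times10^8 / 5\times10^9$ cells/mL), keeping drug-per-cell constant.
Published protocols sometimes state working concentrations that do not
follow from any one scaling convention, so the function reports the
formula values and asserts nothing else. `suspension_hematocrit()` is
the accompanying sanity check: $5\times10^8$ cells/mL at 84.6 fL occupy
4.23% — inside the 4–4.5% band a washed suspension is prepared to.

# Numerical conventions and edge cases

* Every generator takes an explicit seed and is bit-reproducible;
  global RNG state is restored after each call.
* Truncated normals are drawn by inverse-CDF, so degenerate SD = 0
  specs are exactly constant.
* Full immediate hemolysis (zero isotonic signal) yields a 100% curve
  rather than a division error; plateaus whose intact signal has
  vanished give `NA` volumes.
* `resistance_summary()` re-applies isotonic regression to
  user-supplied curves, so raw noisy curves are accepted.
* Quantile-type choices: `calibrate_cutoff()` uses the left-continuous
  empirical quantile (type 1), which makes tail mass 0 return the
  sample minimum and makes the calibrate-then-count loop consistent to
  one cell.

# Worked example

```{r example, eval = FALSE}
ctrl <- population_spec(n_cells = 5000, seed = 1)
trt  <- population_spec(n_cells = 5000,
                        lysis_osm = list(mean = 135.6, sd = 8),
                        seed = 2)
rec_c <- simulate_oft_recording(sample_population(ctrl),
                                noise_sd = 0.01, seed = 3)
rec_t <- simulate_oft_recording(sample_population(trt),
                                noise_sd = 0.01, seed = 4)
resistance_summary(lysed_fraction_curve(rec_c))$h50 -
  resistance_summary(lysed_fraction_curve(rec_t))$h50
```

# Known limitations

The scattering model is a projected-area caricature: it reproduces the
directions and relative magnitudes of the swelling and hemolysis
signals, not absolute instrument units, and the $V^{2/3}$ inversion is
exact only within that model. The tracker assumes non-overlapping,
darker-than-background cells moving along the channel axis; crossing or
overlapping cells within the displacement gate can swap identities. The
unmixing is only as good as the supplied extinction matrix, and the
three-species set excludes carboxy- and sulf-hemoglobin. Group
statistics implement the two standard branches only — no Welch
correction or mixed models.
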