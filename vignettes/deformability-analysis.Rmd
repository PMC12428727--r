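---
title: "Measuring and modelling RBC deformability with rbcdeform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling RBC deformability with rbcdeform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcdeform)
```

## The measurement model

Red blood cells attached to a slide and exposed to a defined shear stress
elongate according to their mechanical state. Each cell is reduced to its
elongation ratio ER = A/B, the ratio of major to minor axis, so ER ≥ 1 by
construction and ER = 1 is a rigid, undeformed cell. A specimen is
characterised not by a single number but by the ER distribution of a large
population — the protocol this package mirrors pools 25–35 fields of
0.1 mm² each, on the order of 10,000–15,000 cells — summarised as:

* **MER**, the median ER (the package's primary selection criterion);
* **AER**, the mean ER;
* **%UDFC** (ER < 1.1), **%LDFC** (1.1 ≤ ER < 1.3), **%HDFC** (ER ≥ 2.5),
  and the remaining intermediate band reported as **%MID**.

Two boundary conventions coexist in practice: strict bands and cumulative
readings off the distribution curve ("≤ 1.1", "≤ 1.3"). The package
defaults to *disjoint half-open bins* `[1,1.1) [1.1,1.3) [1.3,2.5)
[2.5,∞)` because only that convention makes the four percentages a true
partition (they must sum to 100, which the tests assert to 1e-9); the
cumulative convention is available via
`threshold_scheme(boundary_convention = "cumulative")`. For continuous
data the boundary choice has measure zero, but it must be deterministic:
values exactly at a threshold always fall in the upper band. The MER is
canonically computed from the raw sample (median with midpoint convention
for even n); `curve_median()` also reads it off the binned cumulative
curve, and the two agree to within one bin width (default 0.05, chosen to
resolve the 1.1 and 1.3 cut points).

Cell-count and field-count protocol targets are advisory:
`aggregate_fields()` warns, but does not fail, outside 10,000–15,000 cells
or 25–35 fields, since they describe protocol coverage rather than
validity.

## Cell detection and axis measurement

The imaging module is deliberately the simplest deterministic chain that
an analytic oracle can check end to end:

1. **Foreground**: one global threshold — Otsu by default, a fixed value
   optionally. Cells are bright on dark; `qc_params(invert = TRUE)`
   handles the opposite dialect. A constant image has no foreground and
   yields an empty table; a fixed threshold that marks > 90% of the field
   as foreground raises a degenerate-threshold error instead of returning
   nonsense.
2. **Components**: connected-component labeling (EBImage). Watershed
   splitting of touching cells is deliberately out of scope — the
   synthetic renderer keeps overlap controllable, and on real data
   touching cells are excluded by QC rather than guessed at.
3. **Axes**: a moment-based ellipse fit. With pixel coordinates x right,
   y down, 0-based, centers on integers, the second-order central moments
   of a component's pixels (plus Sheppard's +1/12 correction for the
   spread of mass within each unit pixel cell) give a covariance matrix
   whose eigenvalues λ₁ ≥ λ₂ define the axis lengths `4√λ` and the
   orientation `atan2(2μxy, μxx − μyy)/2`. An ideal filled ellipse is
   recovered exactly in the continuum limit; at RBC scales the remaining
   error is rasterization. Masks of one pixel or with zero raw minor
   variance (collinear) are degenerate and flagged rather than measured.

Rasterization accuracy depends on the sub-pixel alignment of the cell.
For a minor axis of 8 px, a generic (non-grid-aligned) position measures
ER to about 1–2%; the grid-aligned case, where the ellipse boundary runs
flat along a pixel row, is the measure-zero worst case at roughly ±6%.
The renderer places cells at continuous positions, so the recovery tests
(per-cell ER error < 3% for minor axis ≥ 8 px) probe the generic
behaviour; fixtures in the unit tests use a generic sub-pixel phase for
the same reason.

Default QC brackets normal RBC geometry: projected area 20–200 µm²,
border-touching components excluded (their axes are not measurable),
ER > 6 flagged as an absurd shape. All flagged components stay in the
output table with a `qc_reason`, so filtering is auditable.

## The synthetic-data model

No instrument data ship with the package; the generators define the study
conditions everything is tested under.

**Within-sample ER distribution.** ER = 1 + a two-part mixture: with
probability `rigid_fraction` a half-normal spike of scale `rigid_spread`
(default 0.03, keeping > 99.9% of the spike below ER 1.1 — cells that
barely deform), otherwise a lognormal with log-sd `tail_shape` and median
`tail_scale`. The support respects ER ≥ 1, the shape is right-skewed with
a near-1 spike, matching measured ER distributions qualitatively, and —
decisive for calibration — the three free parameters map one-to-one onto
a (MER, %UDFC, %HDFC) target triple. A gamma tail was considered for the
deformable component and rejected: with the median pinned, a gamma cannot
simultaneously produce a small %UDFC (light lower tail) and a large %HDFC
(heavy upper tail) of the magnitudes seen in per-unit profiles (e.g. MER
1.55 with %UDFC 1.12 and %HDFC 6.14), whereas the lognormal solves such
triples exactly. No within-sample variance figures are published for
these populations, so the distributional form is a declared convention of
this package, recorded in every simulation manifest.

**Calibration.** `calibrate_population()` solves the three constraints
with closed-form updates inside a damped fixed point (tolerance 1e-3 on
the probability scale, typically converging to machine precision in tens
of iterations; deterministic, no RNG). The rigid fraction comes from the
%UDFC constraint, the log-sd from %HDFC, the log-median from the median
constraint. Degenerate regimes are handled explicitly: %UDFC > 50 flips
to a rigid-dominated solve where the spike carries the median; a %UDFC
target below the floor contributed by the deformable component clamps the
rigid fraction at zero and warns with the achieved value; structurally
impossible targets (percentages outside range, MER outside (1, 2.5))
raise calibration-infeasible errors.

**Cohorts.** A cohort preset carries between-unit means and SDs of MER
and %UDFC plus the group size. The built-ins encode the two reference
groups: stored packed RBC units (MER 1.52 ± 0.11, %UDFC 3.18 ± 3.83,
n = 156) and cord-blood RBCs (MER 1.61 ± 0.07, %UDFC 2.21 ± 1.06,
n = 78). Per unit, targets are drawn from truncated normals (MER ≥ 1.05,
%UDFC ≥ 0), a model is calibrated (%HDFC left to the default log-sd 0.65,
so %LDFC/%HDFC emerge from the calibrated shape instead of
over-constraining four correlated targets), and 10,000 ERs are sampled by
default.

**Field images.** Cells render as filled ellipses, axis ratio equal to
their ER, projected area drawn from N(55, 8²) µm² (an undeformed disc of
~8 µm diameter; area is preserved under elongation), major axis along the
flow (+x) with 5° angular jitter. Placement is rejection sampling with a
2-px separation margin so components never merge under the labeler; a
field too crowded to place raises a placement-failure error rather than
silently overlapping. Pixel size defaults to 0.25 µm/px (a high-NA 40×
scale), making a 0.1 mm² field 1265 px square and keeping the smallest
plausible minor axes above ~13 px. Optional Gaussian blur and additive
noise sit on top; intensities clip to [0, 1].

What the generator does **not** emulate: optics (no point-spread function
beyond isotropic blur, no illumination gradients), touching or partially
attached cells, non-elliptical deformed shapes, debris, and any
biophysics linking the 3.0 Pa shear to ER — presets encode outcomes, not
mechanics. Passing recovery tests therefore demonstrate the correctness
of the measurement chain on idealised fields, not robustness to every
real-world artefact.

**Proteomics.** Ln(LFQ) predictor levels are independent normals
(mean 25, sd 1.5); the response is `a·[protein] + b·[HBB] + intercept +
noise` with defaults a = 0.02, b = 0.03, intercept 0.3 and residual sd
0.045, chosen so the population multiple correlation of the combined
two-predictor model is ≈ 0.77 at the default predictor spread — the
strength regime reported for combined protein + membrane-bound-HBB
correlations. The noiseless predictor is kept as `true_response` so rank
agreement between predicted and true deformability can be measured.

## Statistics

Normality is screened with Shapiro–Wilk; `compare_groups()` uses the
pooled-variance Student t-test by default (Welch behind a flag), reports
means, SDs, extremes and per-group normality p, and warns when a group
looks non-normal with fewer than 30 units — the regime where the t-test's
large-sample robustness argument does not apply. No multiple-testing
correction is applied across the five deformability parameters by default
(raw per-parameter p-values are the convention here); a Bonferroni column
is available.

Unit ranking compares each unit's MER to the recipient's with an equality
tolerance. The tolerance is nowhere quantified in practice, so 0.01 MER
units — well inside the sampling noise of a 10,000-cell median — is a
declared convention. Selection takes all `higher` units, else all
`equal_within_tol` units, else falls back to the maximal-MER unit with a
warning; %UDFC (lower is better) is an optional secondary sort.

The biomarker fit is ordinary least squares. R is `sqrt(R²)` — for a
single predictor the absolute Pearson correlation — and p is the overall
F-test, which coincides with the two-sided correlation test for one
predictor. An intercept is included by default even though the bare
two-coefficient equation omits one: without centering, "R" loses its
Pearson meaning (the no-intercept variant exists behind a flag and
reports the fitted–observed correlation instead). The response defaults
to MER with AER as the supported alternative, and the choice is carried
in the fit metadata. Non-positive LFQ intensities are missing values —
the standard label-free convention — never log-imputed by default; units
missing a predictor are excluded from fits (with counts) and flagged
`unrankable` in prediction-based selection. Near-collinear predictors
(condition number > 1e8) warn but still return the fit.

## Problem sizes and reproducibility

All generators are deterministic given a seed; the pipeline runner
derives stage seeds from one master seed, writes the resolved
configuration and its hash next to every report, and reruns are
byte-identical. The test-suite and acceptance-script scales are the
package's own choices: 1,000 random samples (n ≤ 500) for the
profile-oracle equivalence; 25 fields × 400 cells (10,000 cells) for
imaging recovery; 50,000 draws for calibration round-trips; 200
replicates of the full 156-vs-78 cohort comparison (2,000 cells per unit,
whose per-unit median sampling error of ~0.007 is an order of magnitude
below the between-unit SDs being detected) plus 500 null replicates at 15
units per arm; 200 replicates for biomarker CI coverage and 1,000 for
null calibration at 15 units.

## Known limitations

* Touching cells are neither split nor modelled; on dense real fields the
  area filter discards merged blobs, biasing sampling toward isolated
  cells.
* The ER distribution family is a modelling convention; real specimens
  may be multi-modal in ways the two-component mixture cannot represent,
  and calibration targets only three summary statistics.
* Axis accuracy degrades below ~8 px minor axes; at the default pixel
  size this corresponds to extreme elongations already flagged by QC.
* The biomarker module starts at the LFQ table: peptide identification,
  spectrum-level FDR and raw mass-spectrometry formats are out of scope.
* Printed group-level statistics of the reference cohorts are used as
  generator presets; the package reproduces their detectability under
  simulation, not the original clinical values.
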