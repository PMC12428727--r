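# rbcdeform

Red blood cell (RBC) deformability — the ability of a cell to elongate
under shear — governs how well transfused blood perfuses the
microcirculation, and it varies widely between stored donor units. For
fragile recipients such as premature neonates, picking a unit whose
deformability is at least as good as the recipient's own cells is a
concrete, measurable selection criterion. `rbcdeform` implements the
computational side of that workflow for R users: from microscopy fields of
slide-attached, shear-deformed cells (or fully synthetic stand-ins) to
per-cell elongation ratios, population deformability profiles,
donor-versus-recipient comparisons, and a membrane-proteomics linear
predictor of deformability.

## The measurements

Each cell imaged under flow-induced shear is summarised by its elongation
ratio

```
ER = A / B
```

where A and B are the cell's major and minor axes (ER = 1 is an
undeformed, rigid cell). A population of 10,000–15,000 cells pooled over
25–35 microscopy fields (0.1 mm² each) yields a deformability profile:

| parameter | meaning |
|---|---|
| MER | median elongation ratio |
| AER | mean elongation ratio |
| %UDFC | undeformable cells, ER < 1.1 |
| %LDFC | low-deformable cells, 1.1 ≤ ER < 1.3 |
| %HDFC | highly deformable cells, ER ≥ 2.5 |

Cells are detected by global Otsu thresholding plus connected-component
labeling; axes come from a moment-based ellipse fit (axis length
`4·sqrt(eigenvalue)` of the pixel covariance with Sheppard's +1/12
correction). Group comparisons use Shapiro–Wilk screening and Student
t-tests; units are ranked against a recipient by MER. The proteomics
module fits

```
MER = a × [Protein] + b × [HBB] (+ intercept)
```

where both predictors are Ln(LFQ) membrane-protein intensities and [HBB]
is the membrane-bound hemoglobin β-subunit; R is the (multiple) Pearson
correlation of the fit.

Because instrument data of this kind are rarely shareable, the package
ships seeded generators for every input: calibrated ER populations
(`calibrate_population()` solves a rigid-spike + lognormal mixture to hit
target MER/%UDFC/%HDFC exactly), rendered field images with ground truth
(`render_field()`), unit cohorts (`simulate_cohort()`), and proteomics
tables with a known linear signal (`simulate_proteomics()`).

## Worked example

```r
library(rbcdeform)

## a recipient population calibrated to printed targets
model <- calibrate_population(target_mer = 1.55, target_udfc_pct = 1.12,
                              target_hdfc_pct = 6.14)
model
#> ER population model: 0.709% rigid (spread 0.03) + lognormal tail (median 0.553, log-sd 0.648)
#>   analytic MER 1.5500, %UDFC 1.120, %HDFC 6.140

## image it, detect cells, profile the specimen
spec <- render_specimen(model, n_fields = 5,
                        params = imaging_params(cells_per_field = 200),
                        seed = 42)
res <- analyze_specimen(spec$images, sample_id = "recipient")
res$profile
#> Deformability profile 'recipient' (n = 999 cells, 5 fields)
#>   MER 1.546   AER 1.656
#>   %UDFC 1.60   %LDFC 18.02   %MID 75.18   %HDFC 5.21   (disjoint_bins)

## rank candidate units against the recipient
units <- simulate_cohort(cohort_preset("PRBC", n_units = 5), seed = 42,
                         cells_per_unit = 10000)
rank_units(cohort_profiles(units), res$profile)
#> Unit ranking vs recipient MER 1.546 (tolerance 0.01)
#>    unit_id unit_mer         diff          verdict
#>  PRBC_U001 1.666387  0.119956029           higher
#>  PRBC_U003 1.624698  0.078266827           higher
#>  PRBC_U004 1.542637 -0.003794076 equal_within_tol
#>  PRBC_U005 1.520746 -0.025684965            lower
#>  PRBC_U002 1.386086 -0.160345023            lower
#> Selected: PRBC_U001, PRBC_U003

## the proteomics predictor on a 15-unit batch
tab <- simulate_proteomics(proteomics_sim_params(), seed = 42)
fit_combined(tab, "flotillin_1")
#> Deformability biomarker fit (n = 15 units)
#>   MER = 0.009696 x [flotillin_1] + 0.04051 x [HBB] + 0.2953
#>   R = 0.806, p = 0.00187
```

The 5-field run above profiles 999 cells, so `analyze_specimen()` warns
that the full protocol (≥ 10,000 cells) was not reached — use 25 fields of
400 cells for a protocol-scale specimen. The MER of 1.546 recovers the
generator's 1.55 target to within sampling error; the two selected units
are exactly those whose deformability exceeds the recipient's; and the
biomarker fit recovers a noisy but significant two-protein signal
(generator truth a = 0.02, b = 0.03).

`run_pipeline(pipeline_config(seed = 1, output_dir = "out"))` chains all
stages (simulate → render → segment → profile → compare → rank →
biomarker) and writes CSV/JSON reports plus a seed- and hash-stamped run
log; reruns with the same seed are byte-identical. A command-line front
end with the same verbs lives at `inst/scripts/rbcdeform`.

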