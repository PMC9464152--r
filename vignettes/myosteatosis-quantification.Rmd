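---
title: "Quantifying myosteatosis from Dixon fat-fraction MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myosteatosis from Dixon fat-fraction MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imatq)
library(dplyr)
```

## The measurement problem

Skeletal muscle fat infiltration (myosteatosis) has two imaging-visible
components. Intermuscular adipose tissue (IMAT) is the macroscopically
visible fat between muscle fibres and muscle groups inside the fascial
boundary; it appears as contiguous bright regions on a fat-fraction (FF)
map. The remaining muscle tissue (MT) additionally carries fat that is
invisible at imaging resolution — small adipocyte aggregates and
intramyocellular lipids — which shows up only as an elevated mean FF of
the MT voxels. A quantitative Dixon acquisition encodes FF per voxel as an
integer 0–1000 (per-mille, i.e. 0–100%).

`imatq` separates the two components inside a supplied region of interest
(ROI) — the fascia lata interior for the thigh, or manually segmented
psoas / erector spinae at vertebral level L2 for the spine — and then fits
the age trends of the resulting measures across a cohort. Segmenting the
fascia itself, and registering masks onto the FF image, are upstream
steps outside this package: masks are assumed index-congruent with the FF
volume.

## Patient-specific histogram thresholding

Because coil profiles, anatomy and fat load differ between subjects, a
fixed FF cut-off misclassifies systematically. Instead the threshold is
derived per subject from the histogram of all ROI voxels:

1. `build_ff_histogram()` bins ROI voxels on a grid tiling 0–100% FF
   (default bin width 1 percentage point; bins are left-closed and
   referred to by their lower edge).
2. `detect_modes_and_minimum()` smooths the counts with a centered moving
   average (default 5 bins) and takes the two highest-prominence local
   maxima as the muscle (lower-FF) and fat (higher-FF) modes. The local
   minimum is the bin with the lowest smoothed count strictly between
   them.
3. `compute_threshold()` places the classification threshold a fraction
   below the minimum: `threshold = (1 - fraction_below) * minimum_ff`,
   with `fraction_below = 0.5` by default — i.e. the threshold sits at
   half the FF of the histogram minimum. Setting `fraction_below = 0.2`
   reproduces the older 20%-below variant used with T1-weighted
   intensities; `0` thresholds at the minimum itself.
4. `classify_voxels()` labels ROI voxels with FF at or above the
   threshold as IMAT and the rest as MT. The masks partition the ROI
   exactly, and raising the threshold can only shrink the IMAT mask.

`segment_roi()` chains the four steps.

### Numerical choices and degenerate inputs

* **Bin width and smoothing window** (1 point, 5 bins) are conventions —
  the upstream analysis software they emulate does not document its
  values — and both are configuration keys.
* **Tied minima.** When the two modes are far apart the smoothed valley
  can be an exactly flat (often zero) plateau, so "the" minimum is a tied
  set. The package reports the middle bin of the tied set by default:
  the plateau edges are artefacts of where each mode's tail happens to
  end, while the midpoint is the unbiased representative of a flat
  valley. This matters: because the threshold is a *fraction of* the
  minimum FF, taking the lowest tied bin drags the threshold into the
  upper tail of the muscle mode and inflates IMAT (on default phantoms it
  cost ~13 Dice points against ground truth). `tie_break = "lowest"` and
  `"highest"` remain available.
* **Boundary rule.** A voxel exactly at the threshold is IMAT
  (`FF >= threshold`); the choice is arbitrary but fixed and documented.
* **Unimodal histograms** (e.g. an ROI that is essentially all muscle)
  are flagged `bimodal = FALSE`, not errors. Classification then refuses
  unless an explicit absolute fallback threshold
  (`fallback_threshold_pct`) is configured — silently guessing would
  contaminate cohort statistics.

## From masks to measurands

`quantify_compartment()` converts the partition into volumes (voxel count
x voxel volume, in cm^3), mean FF over the ROI and over MT (per-mille
/ 10 = percent), and the ratios IMAT/ROI, MT/ROI, IMAT/MT. Exact
identities — IMAT + MT volume = ROI volume, IMAT/ROI + MT/ROI = 1 — hold
by construction and are enforced in tests. An empty MT compartment
reports a *missing* MT FF rather than zero. Single-slice spine
acquisitions run through the same code with grid depth 1; their "volumes"
are one-slice volumes (area x slice thickness), matching how
single-slice paraspinal results are conventionally reported in cm^3, and
are flagged `single_slice`.

`average_bilateral()` merges left/right psoas or erector results: volumes
arithmetically, ratios recomputed from the averaged volumes. For FF the
unweighted mean of the two sides is primary — the plain reading of
"average of left and right" — with the volume-weighted mean (equivalent
to pooling both sides' voxels) reported alongside.

`normalize_record()` adds IMAT volume and MT FF divided by BMI and by
appendicular skeletal muscle mass (ASMM). The published axes for the
BMI-normalized quantities carry presentation factors (10^4 cm^5/kg,
10^2 cm^2/kg); numerically those equal the plain quotients, so the
default scale factors are 1 and the powers of ten live in the unit
strings.

## Age-trend statistics

`fit_age_trend()` fits ordinary least squares of a measure on age —
closed-form normal equations, authored here and cross-checked against
`stats::lm()` in the test suite — and reports:

* `SEE = sqrt(RSS / (n - p))`, the standard error of the estimate;
* `R^2`; a two-sided slope t-test (linear) or overall F-test (quadratic);
* `%CV = 100 * SEE / mean(y)`;
* the **annual percent change relative to age 20**,
  `100 * slope / (intercept + 20 * slope)` — the yearly change as a
  percentage of the fitted value at the young-adult reference age. This
  statistic is only reported when the regression is significant
  (`p < alpha`, default 0.05, two-sided, no multiple-testing
  correction), mirroring how such tables blank the cell for
  non-significant rows. When the fitted value at the reference age is
  near zero the statistic explodes; it is still returned — genuinely
  huge values (e.g. ~400%/y for an IMAT/MT ratio that is almost zero at
  age 20) are real features of the linear fit — but with a warning,
  because such values must be interpreted with caution.

`build_trend_table()` applies this across measures (listwise deletion per
measure, retained n reported). With `degree = 2` it fits quadratics and
reports gated segment changes via `segment_percent_change()`:
`100 * (y(b) - y(a)) / y(a)` on the fitted curve, by default over 20–40
(relative to age 20) and 40–70 (relative to age 40). Fits carry
`tidy()`/`glance()` methods and `autoplot()` (solid line for linear,
dashed for quadratic).

`reference_trends()` ships the published linear-regression summaries for
healthy males aged 20–70 (thigh, n = 48; psoas and erector spinae at L2,
n = 44) as a tibble — usable as generating parameters for simulations and
as worked-example inputs:

```{r}
rt <- reference_trends()
thigh_imat <- rt |> filter(site == "thigh", measure == "imat_volume_cm3")
annual_percent_change(thigh_imat$slope, thigh_imat$intercept)
```

One published row is arithmetically anomalous: the psoas MT FF
coefficients (slope 0.065, intercept 3.4) give 1.4 %/y while the source
table prints 1.5. The table value is kept verbatim and the row is flagged
`pct_anomaly`.

## What the synthetic data emulate — and what they do not

Ground truth for a segmentation of unpublished per-subject images cannot
be reproduced, so validation rests on two generators.

**`generate_ff_phantom()`** builds a digital phantom: elliptical ROI
masks (one fascia-lata ellipse per slice, or four lateral ellipses for
the spine layout on a depth-1 grid); adipose voxels chosen as the top
`imat_fraction` quantile of a Gaussian-smoothed noise field inside the
ROI, so IMAT forms spatially connected clumps (correlation length
`clump_scale_mm`, default 4 mm) rather than salt-and-pepper noise —
IMAT is by definition *visible, contiguous* fat storage; FF drawn
per voxel from two Gaussians (defaults: muscle 40 +/- 15 per-mille,
about the ~4% MT FF of young adult muscle; fat 850 +/- 50), rounded and
clipped to [0, 1000]. The quantile construction makes the realized
adipose fraction match the target almost exactly, and a fixed seed makes
phantoms bit-reproducible.

The phantom deliberately omits partial-volume mixing, bias fields,
chemical-shift artefacts and anatomy. Consequently its histogram valley
is emptier than a real one, recovery is easier than on real data, and the
per-voxel noise levels are conventions (no published per-voxel
characterization exists to copy). Passing the Dice >= 0.95 recovery tests
therefore demonstrates correctness of the algorithmic chain, not clinical
segmentation accuracy.

**`generate_cohort()`** inverts the regression model: ages uniform on
[20, 70] (the study design range), `value = intercept + slope * age +
N(0, residual_sd)` per measure, with `residual_sd` set to the published
SEE when emulating the study. With `residual_sd = 0` refitting recovers
the generating coefficients to floating-point accuracy — the basis of the
end-to-end inversion tests — and with noise at the SEE level the 95%
slope CIs cover the generating slope at nominal rate over hundreds of
seeded replicates. What this does *not* emulate: the real joint
distribution across measures (each measure's residual is drawn
independently), non-uniform age sampling, and any non-linearity beyond
the quadratic machinery.

Test problem sizes (phantom grids of ~32–64 voxels per side, cohorts of
44–48, 300–500 Monte-Carlo replicates) were chosen so the full suite
exercises every claim in seconds while keeping Monte-Carlo error well
below the tolerances asserted.

## End-to-end runs

`run_pipeline()` takes a subject manifest (in-memory objects or NIfTI
paths), applies the segmentation and quantification chain per subject —
averaging bilateral compartments in `spine_L2` mode — normalizes, and
fits the cohort trend table when at least three subjects with ages
survive. Failures are per-subject: a subject with a corrupt image or an
unresolvable histogram is dropped and counted, and the cohort stage runs
on the survivors, as real cohorts lose scans to motion artefacts. Every
bundle embeds provenance (package version, full configuration and its
hash, per-subject thresholds); `write_results()` emits per-subject JSON
plus cohort and trend CSVs. All file formats are NIfTI (images/masks),
CSV (tables) and JSON (config/results).

```{r, fig.width = 6, fig.height = 4}
ph <- generate_ff_phantom(phantom_spec(grid_shape = c(48, 48, 4), seed = 1))
seg <- segment_roi(ph$volume, ph$roi_masks$fascia_lata)
autoplot(seg$histogram)
dice_coefficient(seg$imat, ph$truth_imat)
```

## Known limitations

* The threshold rule is the multiplicative reading of "a fraction below
  the minimum"; an additive offset in FF points is an alternative reading
  and can be emulated only approximately via `fraction_below`.
* Intra- and extramyocellular lipids cannot be separated from MT FF by
  imaging; that distinction needs spectroscopy and is out of scope.
* No mask registration or fascia segmentation: garbage masks give
  garbage quantities, subject only to the binary/congruence checks.
* The annual-percent-change statistic is undefined when the fitted value
  at the reference age is zero and unstable near it; downstream
  consumers should heed the instability warning rather than silence it.
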