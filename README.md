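# imatq

Quantification of myosteatosis — skeletal muscle fat infiltration — from
Dixon fat-fraction (FF) MRI, for imaging scientists and musculoskeletal
researchers studying sarcopenia and muscle ageing.

Inside a supplied region of interest (the fascia lata interior of the
thigh, or psoas / erector spinae at L2), the package separates
**intermuscular adipose tissue (IMAT)** from **muscle tissue (MT)** with a
patient-specific threshold derived from the bimodal histogram of ROI
fat fractions: the two highest-prominence modes (muscle low-FF, fat
high-FF) are located on the smoothed histogram, the local minimum between
them is found, and the classification threshold is placed a fraction
below it,

```
threshold = (1 − fraction_below) · FF(local minimum),   fraction_below = 0.5
```

Voxels with FF ≥ threshold are IMAT, the rest MT. From the partition it
computes volumes, fat fractions, ratios (IMAT/ROI, MT/ROI, IMAT/MT) and
BMI/ASMM normalizations, then fits per-measure age trends by ordinary
least squares with the derived statistics

```
SEE = √(RSS / (n − p))          %CV = 100 · SEE / ȳ
annual %change (ref. age 20) = 100 · slope / (intercept + 20 · slope)
```

gated on two-sided significance (α = 0.05), plus quadratic fits with
segment percent changes (20→40 relative to age 20, 40→70 relative to
age 40). A phantom generator with voxel-level ground truth and a cohort
generator that inverts the regression model make every stage testable
without patient data; `reference_trends()` ships the published
linear-trend coefficients for healthy males aged 20–70.

## Worked example

```r
library(imatq)

# phantom with known ground truth: 10% IMAT, muscle 40±15 ‰, fat 850±50 ‰
ph  <- generate_ff_phantom(phantom_spec(grid_shape = c(48, 48, 4), seed = 1))
seg <- segment_roi(ph$volume, ph$roi_masks$fascia_lata)
seg$histogram
#> <ff_histogram> ROI 'fascia_lata': 4176 voxels, 1%-wide bins
#>   modes: muscle 4.0%, fat 84.0%; minimum 40.0%
#>   threshold: 20.00% FF
dice_coefficient(seg$imat, ph$truth_imat)
#> [1] 1

quantify_compartment(ph$volume, ph$roi_masks$fascia_lata, seg$imat, seg$mt)
#>   roi_volume_cm3 imat_volume_cm3 mt_volume_cm3 roi_ff_pct mt_ff_pct imat_over_roi
#>           12.528           1.254        11.274     12.098     3.981           0.1
```

The detected muscle and fat modes sit at 4% and 84% FF; the minimum
between them (40%) halves into a 20% threshold, which recovers the
generated IMAT mask exactly (Dice = 1) and a 10.0% IMAT volume fraction.
The MT fat fraction of 3.98% matches the generating muscle distribution
(40 ‰ ≈ 4%).

Cohort-level statistics work on any data frame with an `age` column —
here the published thigh IMAT trend:

```r
rt <- reference_trends()
r  <- subset(rt, site == "thigh" & measure == "imat_volume_cm3")
annual_percent_change(r$slope, r$intercept)
#> [1] 1.923077   # printed as 1.9 %/year
```

i.e. thigh IMAT volume grows by 1.9% of its age-20 value per year.
`run_pipeline()` chains segmentation → quantification → normalization →
trend table over a subject manifest (NIfTI paths or in-memory objects)
and `write_results()` writes per-subject JSON plus cohort/trend CSVs.

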