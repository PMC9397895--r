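# musclevol

Muscle volume estimation from serial MRI cross-sectional areas, and the
accuracy cost of analysing fewer slices.

## The problem

Quadriceps muscle volume (MV) is a key muscle-mass outcome in sarcopenia
research — including end-stage liver disease, where low muscle mass predicts
complications and mortality — but obtaining it requires manually segmenting
the anatomical cross-sectional area (ACSA) on every axial MRI slice of a
region of interest. Widening the slice interval from 1 cm to 2–4 cm cuts
that workload by up to 75%. `musclevol` quantifies what that costs: it
estimates MV from an ACSA series with the two standard equations, subsamples
series to coarser intervals, and computes the error and agreement statistics
used to judge whether the shortcut is acceptable.

For areas $A_0,\dots,A_{N-1}$ (cm²) at slice spacing $\Delta$ (cm):

* **Cylindrical (Cavalieri):** $MV = \sum_n A_n \Delta$ — each slice
  extruded over one interval.
* **Truncated cone (frustum):**
  $MV = \sum_n \frac{\Delta}{3}\bigl(A_n + \sqrt{A_n A_{n+1}} + A_{n+1}\bigr)$
  — exact for conical segments.

Agreement against the 1 cm reference is summarised by absolute/relative
error, Bland–Altman mean bias with 95% limits of agreement, two-way mixed
ICC(3,1) for inter-rater reliability, and Pearson correlation (e.g. against
L3 skeletal muscle index). A phantom module generates synthetic quadriceps
cohorts with analytically known volumes, so every estimator is validated
against exact ground truth.

## Worked example

```r
library(musclevol)

## one noiseless series sampled from the default quadriceps template
s <- ACSASeries("demo", positions = 0:22,
                areas = areaAt(quadricepsPhantom(), 0:22))
c(cylinder = volumeCylinder(s), cone = volumeTruncatedCone(s),
  truth = analyticVolume(quadricepsPhantom()))
#>  cylinder      cone     truth
#> 1000.5631  964.0275  964.3912
```

The cone (which covers the 22 cm between first and last slice) lands within
0.04% of the analytic truth; the cylinder covers one extra interval beyond
the last slice, hence its larger raw value.

```r
## the full slice-interval experiment on a synthetic 38-subject cohort
coh <- generateCohort(cohortSpec(nSubjects = 38, seed = 1))
vols <- do.call(rbind, lapply(coh$series, runIntervalExperiment))
summarizeByCell(computeErrors(vols))
#>         equation interval_cm mean_bias_cm3 loa_low_cm3 loa_high_cm3 n_within_loa mean_abs_err_cm3 mean_rel_err_pct
#> 1       cylinder           2        4.3392     -0.5614        9.240           36            4.471           0.4410
#> 2       cylinder           3       10.0572      3.5483       16.566           37           10.057           0.9966
#> 3       cylinder           4       15.2016      5.3341       25.069           36           15.202           1.4912
#> 4 truncated_cone           2        0.8864     -3.7576        5.530           36            1.981           0.2035
#> 5 truncated_cone           3        3.2037     -3.1417        9.549           36            3.786           0.3918
#> 6 truncated_cone           4        5.0027     -3.1163       13.122           35            5.447           0.5518
```

Reading the table: both equations *underestimate* at coarser intervals
(positive mean bias, reference minus comparison), the error grows with the
interval, about 95% of subjects fall within the Bland–Altman limits of
agreement, and the truncated cone's mean relative error stays under 1% at
every interval while the cylinder's approaches 1.5% at 4 cm — the cone
tolerates slice thinning markedly better over a restricted ROI.

End-to-end runs (cohort generation or CSV/NIfTI input, ROI restriction,
experiment, reports, plots) go through `runStudy()` with a YAML or list
config; a thin CLI lives at `inst/scripts/musclevol.R`.

## Documentation

The methods vignette (`vignettes/muscle-volume-estimation.Rmd`) documents
the estimators, the end-segment handling at coarse intervals, the agreement
statistics, the phantom generator's design and its calibration, and known
limitations.
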