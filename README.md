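# bmareader

Spot calling, calibration and panel statistics for slide-format
fluorescence **biomarker microarrays** (BMA), as imaged one well at a
time by an RGB-camera point-of-care reader.

A BMA well carries a small grid of printed antibody spots — five
analytes in triplicate plus printed controls (BSA-biotin positives,
PBS negatives).  After a sandwich assay with a Cy3 reporter, the well
is photographed and everything downstream is image analysis and
statistics.  This package implements that onboard analysis chain as a
reusable, fully testable toolkit:

1. **Spot calling** — the red channel of the RGB frame (which carries
   the Cy3 emission) is smoothed with a normalized 9×9 Gaussian kernel,
   thresholded (`mean + k·sd`, absolute, or percentile), and segmented
   into labelled contours; contours with area < 100 px or circularity
   `4πA/P² < 0.6` are rejected as dust and debris.
2. **Grid anchoring** — detected centroids of the positive control
   spots (C1–C3 anchors; C4/C7 bounds) are assigned to the declared
   layout by optimal one-to-one matching and a similarity transform is
   fitted; test-spot regions are localized within a bounded search
   range on either side of the anchor row, clipped by the C4–C7
   rectangle.
3. **Quantification** — each spot's mean intensity over its aperture
   minus the median of a local annulus, with an annulus-based SNR;
   triplicates are aggregated (mean, CV) and normalized to the well's
   positive-control signal.
4. **Calibration** — four-parameter logistic standard curves

   y(x) = d + (a − d) / (1 + (x/c)^b)

   fitted by deterministic least squares (`fourpl` objects with
   `print`, `coef`, `predict`, `plot`, `residuals` methods), with the
   closed-form inverse x = c·((a − y)/(y − d))^(1/b) for concentration
   estimation.
5. **Panel statistics** — Welch t tests, ROC/AUC with DeLong
   confidence intervals (logit-scale by default), combined panel
   scores, Pearson/Spearman cross-platform correlation, and a GenePix
   GPR/ATF reader for scanner comparisons.
6. **Synthetic slides** — a deterministic renderer draws
   Gaussian-profile spots, background planes, pixel noise and dust on
   a desk-scale 1024×768 stand-in for the native 4056×3040 sensor,
   and emits exact ground truth (centres, per-spot footprint means),
   so every stage can be validated without instrument data.
   `simulate_cohort()` builds entire imaged case-control cohorts with
   designed per-analyte AUCs.

## Worked example

```r
library(bmareader)

layout <- default_layout()
scene  <- render_synthetic_array(scene_config(layout = layout,
                                              noise_sigma = 6, seed = 42))
calls  <- process_well(scene$image, layout, well_id = "demo")
head(calls[, c("label", "role", "analyte", "x", "y", "net", "snr")], 5)
#>      label             role analyte     x     y   net    snr
#> 1       C1 control_positive    <NA> 153.5 192.1 75.53 11.818
#> 2       C2 control_positive    <NA> 512.0 191.9 76.96 11.963
#> 3       C3 control_positive    <NA> 870.5 192.0 75.67 11.893
#> 4       C4 control_positive    <NA> 153.6 284.2 75.82 11.875
#> 5 VSIG4-r1             test   VSIG4 255.9 284.3 33.66  5.427
```

All 22 spots are localized to sub-pixel accuracy; `net` is the
background-subtracted mean intensity.  Replicates aggregate and
normalize against the positive controls:

```r
normalize_intensity(aggregate_replicates(calls), calls)
#>    analyte n mean_net       cv missing normalized
#> 1    VSIG4 3    33.44 0.006987   FALSE     0.4402
#> 2      OPN 3    46.44 0.002618   FALSE     0.6115
#> 3    VCAM1 3    58.94 0.015122   FALSE     0.7760
#> 4    ALCAM 3    71.92 0.011275   FALSE     0.9469
#> 5 TNFRSF1B 3    84.32 0.004700   FALSE     1.1103
```

The replicate CVs are ~1%, and the normalized values recover the
rendered amplitude ladder (80/110/140/170/200 against positive
controls at 180).  Standard curves and inverse prediction:

```r
x <- rep(5 * 3^(-3:3), each = 3)                     # 7-pt 3-fold series
y <- 60000 + (10 - 60000) / (1 + (x / 5)^1.2)
fit <- fit_4pl(x, y)
fit
#> Four-parameter logistic standard curve
#>   y = d + (a - d) / (1 + (x/c)^b)
#>   a = 10   b = 1.2   c = 5   d = 60000
#>   R-squared: 1.000000   (nls-port)
invert_4pl(fit, predict(fit, newdata = 5))
#> [1] 5
```

An imaged cohort (10 healthy controls vs 10 cases, designed AUCs
0.80–0.95) runs end to end through rendering, spot calling,
normalization and ROC analysis:

```r
coh <- simulate_cohort(seed = 7)
panel_stats(coh$values, coh$labels)
#>    analyte t_statistic  p_value  auc ci_low ci_high
#> 1    VSIG4       3.461 2.81e-03 0.86  0.577   0.965
#> 2      OPN       3.898 1.23e-03 0.92  0.706   0.982
#> 3    VCAM1       5.838 1.57e-05 0.97  0.770   0.997
#> 4    ALCAM       0.979 3.48e-01 0.56  0.297   0.793
#> 5 TNFRSF1B       6.393 9.33e-06 0.99  0.858   0.999
#> 6    panel          NA       NA 1.00  1.000   1.000
```

ALCAM (designed at 0.85) illustrates small-cohort sampling noise: this
seed's biological draw happened to separate poorly, and the wide DeLong
interval reports exactly that.

A command-line wrapper for batch runs lives at `inst/cli/bma-reader.R`
with subcommands `simulate`, `call`, `profile`, `fit`, `quantify`,
`stats`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end chain from scratch — renders a
well, calls and quantifies its spots, fits and inverts a standard
curve, and runs cohort panel statistics — and writes the results JSON
to `--out`.
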