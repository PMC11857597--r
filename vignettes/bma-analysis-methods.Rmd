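---
title: "Methods: spot calling, calibration and panel statistics for biomarker microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot calling, calibration and panel statistics for biomarker microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmareader)
```

# The measurement problem

A biomarker-microarray (BMA) well contains a few dozen printed antibody
spots: five analytes in triplicate plus printed controls — BSA-biotin
positives that always fluoresce, and PBS negatives that never should.
After a sandwich assay with a Cy3 reporter, a camera photographs the
well and every number downstream (net spot intensity, analyte
concentration, per-analyte AUC) is a function of that one RGB frame.
This vignette documents the analysis model the package implements, the
parameters that matter, and the numerical and design choices made where
more than one defensible option existed.

# Spot calling

The chain is: red channel → Gaussian smoothing → intensity threshold →
connected components → area/circularity gate → centroids.

**Red channel.** Cy3 emission dominates the camera's red channel, so
`extract_red_channel()` takes the first plane with no scaling.  The
pixel convention is fixed throughout: `x` = column, `y` = row, 0-based,
origin top-left.

**Smoothing.** `gaussian_blur()` convolves with a normalized, truncated
9×9 Gaussian (`blur_kernel = 9`).  The kernel sigma is not dictated by
the instrument; the default uses the common kernel-size rule
`0.3·((k−1)/2 − 1) + 0.8` (≈ 1.7 px at k = 9) and is exposed as
`blur_sigma`.  Border handling is symmetric reflection (the edge pixel
is repeated).  This convention was chosen deliberately: it makes the
smoothing operator symmetric and doubly stochastic, so a constant frame
stays constant *and* the total pixel sum is conserved — both properties
are asserted in the test suite.  The half-sample ("reflect-101")
convention preserves constants but not mass.

**Threshold.** The instrument's own threshold rule is not published
beyond "intensity-based", with an explicit caveat that Otsu's method
struggles on non-bimodal fluorescence histograms.  The default is
`mean + 3·sd` of the *blurred* frame — robust for sparse bright spots
on a dark background, because the mean and sd are dominated by
background pixels.  Absolute and percentile modes are selectable
(`threshold_mode`), and thresholding the raw frame instead is just a
matter of passing it.

**Contours.** Connected components (8-connectivity by default) are
extracted by frontier breadth-first search; a brute-force flood-fill
oracle cross-checks it on random masks in the tests.  Centroids are
unweighted means of member pixel coordinates — with an isotropic spot
profile, intensity weighting adds nothing and the unweighted mean is
noise-robust.  Perimeter uses the weighted border-pixel estimator
(straight runs weight 1, diagonal steps √2, corner configurations
(1+√2)/2), which is close to unbiased for smooth digital shapes:
digital discs score ≈ 0.92 on circularity `4πA/P²`, squares ≈ 0.97,
a 3×30 bar ≈ 0.29.  Circularity is clamped at 1 because discretization
can push the raw ratio above the continuous maximum; 1–2 px specks
have no measurable boundary and report perimeter 0 / circularity 1 —
the area gate is what removes them.

**Gate.** Contours with area < `min_area` (default 100 px, the
instrument's experimentally determined minimum spot size; the boundary
is inclusive — exactly 100 px survives) or circularity <
`min_circularity` (default 0.6) are discarded.  The circularity gate
operationalizes "circular contours": it passes discs and compact blobs
and rejects elongated smears, while dust below the area cut is removed
regardless of shape.

# Grid anchoring and quantification

**Control assignment.** Only positive-role controls can be detected
(PBS negatives carry no dye), so the grid is anchored on C1–C4 and C7.
Expected layout positions are rescaled from the layout's reference
raster (4056×3040 by default) to the frame, then assigned to detected
contours by optimal one-to-one matching (Hungarian algorithm,
`clue::solve_LSAP`) on centroid distance.  A similarity transform
(translation + isotropic scale; rotation optional and off by default,
since slide seating is dominated by shift and scale) is fitted by least
squares on the assigned pairs; an RMS residual above `residual_tol`
(default 10 px) aborts with an alignment error rather than quantifying
a mis-registered well.

**Bounded search.** Test-spot positions are mapped through the
transform and accepted only if they lie within `search_range`
(1200 px at reference scale, rescaled proportionally) of the anchor-row
axis on either side *and* inside the rectangle spanned by the mapped C4
and C7 centroids.  The rectangle is applied with 0.5 px slack: detected
bound centroids jitter by fractions of a pixel and the outer spot rows
sit exactly on the bound rows, while a spot a full pixel beyond the
bounds is still flagged missing.

**Quantification.** Each spot is measured as the mean raw intensity
over a fixed circular aperture — the disc inscribed in its ROI (side
`2·radius·scale`, minimum 9 px) — re-centred on the detected contour
centroid when one falls inside the ROI.  The background is the median
of a square annulus around the ROI (inner margin 2 px, outer 8 px),
excluding pixels of any other ROI; the median is robust to tails of
neighbouring spots.  SNR is net intensity over the annulus standard
deviation; with a perfectly flat noiseless background the SNR of an
empty spot is defined as 0.  A design note: an alternative is to
integrate over the detected contour itself, but the contour's extent
depends on the threshold — dim spots yield small contours whose mean
overstates the spot, bright spots yield large contours that dilute it —
biasing net intensity by tens of percent.  The fixed aperture matched
to the expected spot radius keeps the net-intensity estimate unbiased
(within ~4% at the defaults, from the annulus picking up faint spot
tails) and is what the recovery tests assert against ground truth.  The
contour still contributes what it is good at: sub-pixel localization.

The `low_snr` flag is disabled by default (`min_snr = 0`): negative
controls legitimately have SNR ≈ 0, and flagging them would discard
exactly the spots that prove the assay's specificity.

# Row profiles

`segment_rows()` partitions the frame into horizontal bands (equal
split with the remainder in the last band, or centred on known row
positions); `row_profile()` reports the column-wise band mean minus the
band median (an option switches to the column maximum, which is
undiluted by band height and better suited to peak counting in wide
bands).  `detect_peaks()` applies height-ordered greedy non-maximum
suppression with a minimum separation; equal-value plateaus count once,
reported at their leftmost pixel, and plateaus touching the profile
edge are not peaks (so a flat profile has none).  These views mirror
the instrument's per-row QC display; whether the original uses the
mean, the maximum or a single scanline per row is unpublished, so the
statistic is a parameter.

# Four-parameter logistic calibration

Standard curves use `y(x) = d + (a − d)/(1 + (x/c)^b)` with `a` the
zero-concentration response, `d` the saturating response, `c` the
inflection (EC50, in the analyte's concentration units) and `b` the
slope factor.  The fit is unweighted least squares (1/y² weighting is
available), deterministic by construction: the start is `a` = mean
response at the lowest concentration, `d` = mean at the highest,
`c` = geometric mean of the nonzero standards, `b` = 1, refined by
bounded Gauss–Newton (`nls`, port algorithm, `c > 0`) with a
Nelder–Mead fallback on the same objective.  Taking the start from the
concentration ends rather than from `min(y)`/`max(y)` orients the start
correctly for both increasing and decreasing curves; recovery to within
1% on noiseless 7-point series is asserted for both directions.
`R² = 1 − SS_res/SS_tot`; a constant response series has `SS_tot = 0`
and is returned as a degenerate flat fit with `R² = 1` by convention,
flagged `degenerate`.

Inversion is closed-form, `x = c·((a − y)/(y − d))^(1/b)`, and is exact
to 1e-9 relative error across the curve's dynamic range for slopes in
the immunoassay-typical 0.5–3 band.  Intensities outside the open
interval between the asymptotes return `NA` with an `out_of_range`
flag — a flagged result, not an error, because out-of-range samples are
routine.  Note an arithmetic limit, not a defect: with steep slopes and
intensities evaluated many decades past the EC50, `y` sits within
~1e-8 of an asymptote and double-precision cancellation alone exceeds
any sub-nanometre identity bound.

**Normalization.** How the instrument normalizes well-to-well is
unpublished.  The package divides each analyte's aggregated net
intensity by the mean net intensity of the same well's positive
controls (BSA-biotin is designated the positive control), which cancels
global illumination and exposure factors — verified in tests by
re-rendering a scene at half gain.  A z-score across the cohort is the
natural alternative and can be applied downstream; it is deliberately
not the default because it destroys the per-well interpretation.

**Replicate CV** uses the sample standard deviation over the mean.

# Panel statistics

Group comparisons are Welch two-sided t tests (unequal variances,
Satterthwaite degrees of freedom).  No multiplicity adjustment is
applied by default — the five biomarkers are reported with raw p
values, as is conventional for a pilot panel — with Benjamini–Hochberg
behind a flag.

**AUC.** `roc_auc()` computes the Mann–Whitney AUC with ties counted
1/2 and orientation fixed so the AUC is the probability that a case
outscores a control.  The variance is DeLong's structural-components
estimator.  The confidence interval is constructed on the logit scale
and mapped back (delta method), the standard small-sample remedy for
the linear interval's failure mode near AUC = 1, where `auc ± z·se`
collapses against the boundary and undercovers; `ci_scale = "linear"`
reproduces the plain interval.  Perfect separation has zero DeLong
variance and degenerates to `[auc, auc]` on either scale — with 10
samples per group this happens with appreciable probability even at a
true AUC of 0.95, which is an honest property of small cohorts rather
than something an interval should hide.

**Combined panel score.** The instrument's combination rule for the
"overall" panel is unpublished.  The default is the mean of
rank-standardized analyte values (ranks scaled to [0, 1]) — simple,
monotone-invariant, and parameter-free; an in-sample logistic
combination is available as an option.  Neither is claimed to be the
original's rule.

# The synthetic world

The renderer emulates what matters to the analysis chain: isotropic
Gaussian spots (peak amplitude per label, width `spot_sigma` = 6 px at
the default 1024×768 desk-scale raster, a ¼-scale stand-in for the
4056×3040 sensor), an additive background plane with optional gradient,
i.i.d. Gaussian pixel noise, hard-disc dust artifacts below the area
cut, 8-bit round-half-up quantization with clipping at 255 (rejected at
configuration time unless saturation is deliberately requested), and a
dim constant in the green/blue channels so frames look like camera
output.  The ground truth records exact centres, the true peak, and the
true mean of each spot's own contribution over its footprint — the disc
of radius `2·spot_sigma`, which is also the measurement aperture's
nominal size, so net-intensity recovery is a like-for-like comparison.

Default amplitudes state two worlds: a **QC slide** (`mode = "qc"`)
where every printed spot fluoresces — positives 180, negative positions
150, and a 80/110/140/170/200 test ladder — used for detection-recovery
checks where all 22 spots must be found; and an **assay well**
(`mode = "assay"`) where PBS negatives are dark, used for cohort
simulation.  Background 20, noise sigma 5 by default; the point spread
is not a reconstruction of the real optics (the true spot diameter in
pixels is unpublished), so all of these are parameters, not claims.

`simulate_cohort()` draws per-sample biology from the binormal model:
case amplitudes are shifted by `√2·Φ⁻¹(AUC)·σ_b` (σ_b = 25 around a
healthy mean of 110), the separation that produces the designed AUC
under equal variances; all three replicates share the sample's
amplitude, so replicate scatter comes entirely from the imaging chain.
Draws are clamped to [1, 230] to respect the renderer's saturation
budget (< 0.5% of draws at the defaults).

What the generator does **not** emulate: optical vignetting and
illumination flat-field structure, spot-morphology defects (doughnuts,
comets, merged spots), autofluorescent background texture, chamber
edges, and any biology beyond a per-analyte location shift.  A green
test suite therefore establishes that the *analysis chain* is correct
on its stated model — it does not certify performance on real slides,
whose headline numbers (standard-curve R² of 0.995–0.999, platform
correlations ≥ 0.95, per-biomarker AUCs of 0.81–0.98) come from
undeposited instrument and patient data.  The package's claims are
property-level: parameter recovery, oracle equivalence, invariances,
and designed-AUC attainment on synthetic cohorts.

# Determinism

Every stochastic element is seeded: a scene's seed fully determines its
pixels (the renderer saves and restores the caller's RNG state), the
cohort seed determines both biology and per-well imaging seeds, the 4PL
fit has no random element, and identical configuration plus seed gives
byte-identical pipeline outputs end to end — asserted as a test.

# Known limitations

- No watershed splitting of merged spots, deconvolution, or
  illumination flat-fielding beyond the local annulus background.
- One well per frame; no whole-slide stitching or layout
  auto-discovery without a declared layout.
- 4PL only (no 5PL), no LOD/LOQ estimation, no curve transfer across
  reagent lots.
- The C4–C7 role assignment (which printed controls are positive) is
  an assumption recorded in the default layout, not a published fact;
  alternative layouts load from JSON.
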