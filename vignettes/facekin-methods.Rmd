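---
title: "Quantifying hypomimia from facial landmark dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hypomimia from facial landmark dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

Hypomimia reduces the *amplitude and frequency* of facial movement. The
package therefore measures, for each facial region, the temporal
**variability** of a per-frame scalar and reports its sample standard
deviation (n − 1 denominator) over all usable frames of a recording. A
perfectly still face scores exactly 0 on every marker; any reduction of
movement amplitude lowers the marker proportionally (the SD is homogeneous
of degree one in the amplitude of the underlying signal). The twelve markers
cover eight regions — forehead, nose root, eyebrows, eyes, lateral canthal
areas, cheeks, mouth, jaw — with seven markers carrying left/right variants
(19 sided values, side-averaged to 12 for cohort analysis; with one side
missing, the available side is used).

Two marker families exist:

* **Euclidean markers** need only the 68-point landmark track. Distances are
  divided by the inner-eye-corner distance (IED, landmarks 39–42), areas by
  IED², so the markers are invariant to face scale and rigid translation;
  the two angle markers (brow tilt against the inter-canthal line, brow apex
  angle) are additionally rotation invariant. The brow tilt line is fitted
  by total least squares (principal axis) through the five brow points,
  which is rotation-equivariant where ordinary regression of y on x would
  not be. The palpebral fissure area uses the shoelace formula on the
  6-point eye contour; self-intersecting contours contribute their absolute
  area.
* **Surface markers** also need the grayscale frames. A landmark-anchored,
  IED-scaled axis-aligned rectangle is resampled bilinearly to a canonical
  64×64 patch, edges are highlighted with 3×3 Sobel kernels (rescaled by
  1/4 so a unit step maps to ≈ 1), and the per-frame scalar is the Shannon
  entropy of a fixed-range 64-bin histogram (range [0, √2] for edge
  magnitudes, [0, 1] for cheek difference images; 0·log 0 ≡ 0). The cheek
  marker uses the entropy of the absolute difference of *consecutive* cheek
  patches, so it sees texture change rather than static texture.

### Declared geometric and numeric defaults

Published descriptions of wrinkle-line markers rarely pin down the ROI
extents or the operators; the defaults here are **declared choices**, all
overridable via `roi_config()`:

* forehead: 1.6 × 0.8 IED rectangle, 0.15 IED above the brow apices,
  centred on the face midline; nose root and lateral canthal: 0.5 IED
  squares (canthal centre 0.35 IED lateral to the outer eye corner along
  the inner→outer corner direction); cheek: 0.7 × 0.9 IED rectangle,
  medial edge at the nose wing, top edge 0.25 IED below the lower-eyelid
  midpoint.
* luminance is normalized by the *representable maximum* (255 for 8-bit),
  never per-frame min–max: per-frame renormalization would erase exactly
  the temporal contrast changes the entropy markers measure.
* entropy is one scalar per frame over the whole patch (not a local entropy
  map), because each marker is defined as the SD of a per-frame scalar.
* patches whose in-frame coverage falls below 0.5 mark that frame unusable
  for that region; markers with fewer than 2 usable frames (or 2 pairs, for
  the cheek) are reported as missing, never as 0.

Any fixed choice here preserves the marker contract the statistics consume
(variability of ROI texture over time); the cohort-level results do not
hinge on the particular extents.

### Gap handling

Frames with any obscured or out-of-frame landmark form gaps. Gaps of at most
one second are retained and filled by per-landmark linear interpolation
between the nearest valid neighbours; longer gaps — and gaps touching the
start or end of the recording, which lack a neighbour on one side — are
excluded and split the recording into segments. The retain/exclude decision
depends only on gap *duration*, not the frame rate. Variability is pooled
across segments; the cheek marker's consecutive-frame pairs never straddle a
segment boundary, so excluded gaps cannot fabricate motion. The fill method
is not dictated by the marker definitions; interpolation is the default and
`fill = "drop"` discards short-gap frames instead.

## Cohort statistics

* **Group differences** (19 sided comparisons): one-sample KS normality
  check on standardized values at α = 0.05 per group; one-way ANOVA when
  both groups pass, Kruskal–Wallis otherwise (also the fallback for a
  zero-variance group). The KS test with estimated parameters is the stated
  procedure and is conservative in this direction; `lilliefors = TRUE`
  switches to the corrected variant. Family-wise error is controlled by
  Bonferroni over the 19 comparisons: 0.05/19 = 0.0026 (4 dp). Two-sided
  p-values throughout.
* **Partial correlations** (12 averaged markers × clinical covariates,
  patients only): x and y are residualized on age by OLS with intercept,
  Pearson r of the residuals, t test on n − 3 df. Complete-case analysis,
  no imputation.
* **Abnormality cutoffs**: per averaged marker, the 5% extreme tail of the
  control distribution *in the direction of impairment*. Since every marker
  decreases with hypomimia, the operational cutoff is the 5th percentile of
  controls with values below it abnormal; the mirrored literal
  95th-percentile reading is available as `direction = "upper"`. A region is
  affected when any of its markers is abnormal (mouth pools its three
  markers, eyebrows pools its three), giving a 0–8 affected-area count.

## Classification

LOSO ridge-logistic regression: for each held-out subject, features are
z-scored with the training fold's statistics and a logistic model with a
weak fixed L2 penalty (λ = 1e−4 on standardized coefficients, intercept
unpenalized) is fitted by IRLS. The penalty exists purely for numerical
stability under (quasi-)separation; plain logistic regression is its λ → 0
limit. AUC uses the rank/Mann–Whitney formulation with midrank ties;
accuracy/sensitivity/specificity are taken at probability 0.5 (a declared
convention). The exhaustive subset search evaluates all 2^k − 1 nonempty
candidate subsets by LOSO accuracy with deterministic tie-breaking (higher
AUC, then smaller subset, then name order). Selection is non-nested — the
reported scores are the selection scores — which mirrors the classical
single-loop procedure and is optimistic for unseen data; treat searched
accuracies as in-sample model selection, not external validation.
Prevalence is estimated at the smallest score threshold whose control
false-positive rate is *strictly* under the 5% bound; with n controls, the
achieved FPR is therefore at most ⌈0.05·n⌉/n − 1/n (4.0% for n = 75).

Known small-sample caveat: under the null, per-fold z-scoring makes LOSO
scores slightly anti-correlated with the labels, biasing AUC below 0.5 at
small n (≈ 0.42 at 20 + 20). This is a property of leave-one-out evaluation
itself, not of the implementation; at 100 + 100 the bias is negligible, and
the package's chance-level checks use label permutations at that size.

## The synthetic cohort generator

No public recordings exist for this task, so the generator is a first-class
module: it defines the study-like conditions under which every downstream
stage is exercised.

* **Geometry**: a neutral 68-point template in IED units, placed in a
  1440×1080 frame at 25 fps by default (the recording format the pipeline
  targets); amplitudes are expressed in IED multiples so recordings are
  self-similar across resolutions, and tests/acceptance render at reduced
  size (e.g. 160×120, 6–10 s) purely to keep problem sizes desk-scale.
* **Dynamics**: sparse upper-face events as Poisson trains of Gaussian
  bumps (brow raises 0.3/s, frowns 0.2/s, blinks 0.25/s, smiles 0.15/s) and
  band-limited 2–7 Hz (syllabic-range) noise for speech-like jaw/lip/corner
  motion; optional slow rigid head translation and white landmark jitter
  (SD 0.01 IED, a realistic tracker-noise floor). **Severity acts
  multiplicatively**: effective amplitude = base × (1 − severity ×
  reduction weight), default weight 0.8 for every signal, so each region's
  marker mean decreases in severity while controls (severity 0) keep full
  amplitude.
* **Rendering**: deliberately low-fidelity procedural grayscale — smooth
  face shading plus wrinkle curves (forehead, glabellar, crow's feet) whose
  contrast tracks the corresponding effective expression signal, and a
  cheek texture displaced by the cheek-raise signal. The texture drive
  scales with the configured base amplitudes, and the cheek displacement
  (up to 0.45 IED) is large enough that inter-frame luminance changes
  clear the entropy histogram's quantization step at low render
  resolutions. Surface markers need texture *dynamics*, not photorealism.
* **Cohort structure**: 75 controls and 91 patients by default, ages
  ≈ 61 ± 11, patient severity ~ Beta(2, 2); clinical covariates derive
  linearly from severity with Gaussian noise (MDS-UPDRS III ≈ 12 + 36·s,
  bradykinesia/rigidity ≈ 6 + 28·s, binding ratios decreasing:
  caudate ≈ 3.6 − 1.2·s, putamen ≈ 2.1 − 1.1·s), matching the magnitude
  and sign structure of a de-novo PD cohort. Controls carry no clinical
  scores or binding ratios. Occlusion gaps arrive at 1/30 s⁻¹ with a 30%
  chance of exceeding one second (and thus being excluded by gating).
* **Determinism**: one master seed; subject i uses the substream seed
  (seed + 1000003·i) mod (2³¹ − 1), so subjects are independent and the
  whole cohort is bit-reproducible.

### What passing tests do and do not show

The generator produces frontal, non-mirrored, fixed-identity faces with
exactly the modelled dynamics; it does not emulate pose changes, lighting
drift, detector bias, glasses/hair occlusion of specific regions, or
between-subject anatomical variation beyond amplitude differences. Passing
the monotonicity, recovery and operating-point suites therefore shows the
*pipeline* is correct and well-calibrated under its stated assumptions — it
does not certify real-world discrimination accuracy, which depends on the
landmark detector and recording conditions.

## Problem sizes used by the test and acceptance runs

Marker monotonicity uses 200 recordings per severity level for the
Euclidean markers (6 s each) and 60 per level for the rendered surface
markers (120×90); chance-level AUC uses 20 label permutations over a
200-subject null cohort; the operating-point run uses the full 91 + 75
cohort with surface markers (6–10 s recordings at 120×90–160×120). These
sizes make every suite reproducible on a single CPU in minutes while
keeping the statistical checks comfortably powered.
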