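---
title: "Kinetic-map texture analysis: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-map texture analysis: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kinetexture)
```

This vignette documents the science behind the package: the kinetic and
texture models, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, and the numerical
and design choices made where the underlying methodology left them open.

## The kinetic model

Each case is a nine-phase single-slice series: a precontrast image
`s_0` and eight postcontrast phases `s_1..s_8` in arbitrary scanner
units. Seven semiquantitative descriptors of the time-intensity curve
are evaluated per lesion pixel (percent scale except MSI, which is in
intensity units): initial and peak enhancement (`E_initial`, `E_peak`),
the early and overall signal-enhancement ratios (`ESER`, `SER`), the
second-phase enhancement (`SEP`), the maximum inter-phase increment
(`MSI`), and the late slope `SI_slope` relative to the mean of the
first two postcontrast phases. `SER > 100%` marks washout kinetics;
`SI_slope < 0` marks a signal that has fallen below its early plateau.

Two conventions needed fixing where the definitions are silent:

* **Peak search.** `s_peak` is the maximum over postcontrast phases
  1–8 only. The peak is a property of contrast enhancement; including
  the precontrast value could only matter for non-enhancing pixels,
  where the ratio maps are meaningless anyway.
* **Degenerate denominators.** A pixel whose denominator magnitude
  falls below `1e-6` times the case's maximum postcontrast intensity is
  marked *invalid* (NaN) for that map rather than evaluated. Invalid
  pixels are excluded from lesion means and texture extraction. For a
  constant series this makes `ESER` and `SER` invalid while
  `E_initial = E_peak = SEP = MSI = SI_slope = 0` remain valid —
  auditable, and consistent with the view that 0/0 is missing
  information, not zero washout.

All maps except MSI are invariant under a global intensity rescaling;
MSI scales linearly. The suite asserts this to 1e-9, together with
closed-form agreement on noise-free synthetic lesions.

## Segmentation

Delineation happens on the third-phase subtraction image (`s_3 − s_0`),
the phase at which both washout and persistent lesions are strongly
enhanced: Otsu's threshold over a 256-bin histogram inside an optional
operator ROI box, selection of the seeded or largest 8-connected
component, hole filling, and a 16-pixel minimum (texture matrices are
ill-defined on smaller regions). The ROI box and seed point model the
radiologist interaction of a semi-automatic workflow; nothing else about
slice or lesion choice is automated. On noise-free synthetic cases the
recovered masks reach Dice 1.0 against the generating ellipse; the
acceptance suite requires ≥ 0.9 over 20 seeds.

## The texture engine

Fifty-five features per map, in four families. Histogram moments (mean,
population variance, skewness, kurtosis) and all DWT features are
computed on raw map values; GLCM and GRLM features on a quantized ROI.

* **Quantization** (default `L = 8`, min–max within the lesion's valid
  pixels). The source methodology never states its quantization; L = 8
  is a common radiomics default that keeps co-occurrence matrices well
  populated on ~200-pixel lesions. A `raw-integer` mode (levels =
  rounded raw values) is provided because published run-length
  magnitudes (High Gray Level Run Emphasis ~1e5) imply a convention
  with large native gray levels; both are logged. Min–max makes all
  matrix features invariant to affine intensity transforms.
* **GLCM**: four distance-1 offsets (0°, 45°, 90°, 135°, chessboard
  metric), symmetric matrices over in-mask pairs only, 19
  Haralick/Soh–Tsatsoulis features (entropies in natural log; sum
  variance centered on sum average; information measures of correlation
  1–2; inverse difference normalized with the |i−j|/L weighting),
  averaged over offsets with at least one admissible pair. Degenerate
  single-level ROIs take the analytic limits (Energy = 1, Contrast = 0,
  Correlation set to 0 by convention).
* **GRLM**: runs are maximal constant-level segments along each angle's
  scan lines, broken at mask boundaries; 11 standard features; run
  percentage uses the in-mask pixel count. Both matrix families are
  verified against brute-force pair/run enumerators on 1000 random
  masked ROIs at 1e-9, and are exactly invariant to 90° rotations and
  mirrorings (the angle set is closed under them).
* **DWT**: the map is cropped to the lesion bounding box, out-of-mask
  pixels imputed with the in-mask mean, mean-padded to at least 8×8,
  and decomposed twice with separable orthonormal filter banks (haar,
  db2, sym4 — named `harr`, `deubechies2`, `symlet4` to match the
  feature list), symmetric boundary extension. The subband scalar is
  the mean absolute coefficient — simple, shift-robust, and zero for
  details of a constant map. The source names subbands but not the
  statistic; this choice is documented rather than inferred.
* **Kurtosis** is Pearson (non-excess, normal ⇒ 3): published feature
  medians near 4.5–5.7 sit on the Pearson scale for mildly heavy-tailed
  data.

## The synthetic cohort: what it emulates, and what a green test means

No patient data accompany the methodology, so the generator *is* the
test bed. Each case is a 96×96 scene: an elliptical lesion (axes 8–25
px), background tissue with mild uniform enhancement (20% over eight
phases), and additive Gaussian noise at SNR 50 (baseline / noise sd; a
Rician option exists). Lesion pixels follow the piecewise curve
`S0 → linear rise to S0(1+A) at t_p → geometric decay by (1−w)` with
class-conditional priors:

* **HER2-positive**: early peak (`t_p = 1`), washout `w ∈ (0.08, 0.18)`,
  amplitude `A ∈ (1.2, 2.0)`, strong short-range heterogeneity
  (`h ∈ (0.25, 0.40)`, `ell ∈ (2, 4)` px).
* **HER2-negative**: persistent enhancement (`t_p ∈ {6,7,8}`,
  `w < 0.02`), `A ∈ (0.8, 1.6)`, weak long-range heterogeneity
  (`h ∈ (0.05, 0.15)`, `ell ∈ (6, 10)` px).

Two structural choices deserve explanation because they were forced by
the mathematics, not tuned to outcomes:

* **The positive-class peak precedes phase 2.** For a linear rise
  peaking at or after phase 2, `ESER = 50%` identically — per-pixel
  amplitude and washout heterogeneity cancel from the ratio — so no
  ESER-map texture difference between classes could exist. An early
  washout peak (the classic type-III curve) is also the clinically
  expected shape for aggressive lesions.
* **Heterogeneity is a shared two-band patch mosaic**, not a smooth
  field: a smoothed Gaussian field discretized into two
  equal-probability bands, applied multiplicatively (`exp(h·g)`) to both
  `A` and `w`. Sharp-boundary subcompartments (viable rim vs
  necrotic-prone core) are what let matrix texture behave the way
  heterogeneous tumors do. Under lesion-wise min–max quantization a
  *smooth* field couples Contrast and Short Run Emphasis to the same
  noise-to-structure ratio, so both fall together as heterogeneity
  grows — the opposite of the reported pattern in which heterogeneous
  (positive) lesions have *higher* Contrast yet *lower* SRE. Piecewise
  constancy decouples them: long runs inside patches, large gray-level
  jumps across boundaries.

One directional property remains out of reach by construction: with
min–max quantization, an iid-noise map sits near the Contrast ceiling,
so Contrast cannot *increase* monotonically from the h→0
(noise-dominated) limit; it falls to the structural level and stays
flat. The property suite therefore asserts the monotone decrease of SRE
with `h` (which holds seed-wise), and the class-level directions
(ESER-SRE lower, E_peak-Contrast higher in positives) are checked on
cohorts, not on the amplitude knob.

A green end-to-end test establishes that the pipeline separates classes
whose kinetics and texture differ as designed, that every stage is
deterministic under its seed, and that each computational primitive
matches an independent oracle. It does *not* establish clinical
performance: the synthetic classes are far better separated than real
HER2 groups (training AUCs here are ≈ 1.0, versus 0.83–0.92 reported on
patients), there is no partial-volume effect, no motion, no
field-inhomogeneity bias, and lesion masks are single ellipses.

## Selection and modeling

The correlation filter iteratively removes, from the most correlated
pair above |r| = 0.95, the member with the larger mean absolute
correlation to the retained set (ties → later canonical column).
LASSO selection z-scores the training features, assigns stratified
folds from the run seed, and takes the nonzero set at the
deviance-minimizing penalty (`lambda.min`, not 1-SE — the later
stepwise stage does its own pruning, so mild over-selection is
harmless; per-fold nonzero sets are recorded). The published
description of "dividing features into 10 groups" is read as the usual
sample-wise stratified 10-fold CV — fold-wise feature subsets would
make the penalized likelihood undefined.

Forward stepwise logistic regression uses likelihood-ratio entry at
p < 0.05 and removal at p > 0.10 (SPSS-like defaults; the methodology
names the procedure but no criteria) and fits by maximum likelihood on
raw features, so coefficients live on the interpretable
`Y = β0 + Σ βi·xi` scale. Complete separation — common on well-separated
synthetic cohorts — is detected by diverging coefficients and resolved
by a lightly ridge-penalized refit (`λ = 0.01`), flagged in the model
record. At the nominal 0.05 entry level, one stray noise feature per
~20 candidates is admitted by design; support-recovery checks therefore
require the true features to be *contained* in the selected set.

ROC analysis ranks all observed cut-points (`call positive iff
Y ≥ t`): AUC is the tie-aware Mann-Whitney statistic (identical to the
trapezoid area, verified against a concordant-pair enumerator at
1e-12), the 95% CI is DeLong's, and the operating threshold maximizes
the Youden index with ties resolved toward sensitivity (screening
context). The threshold is frozen on the training set and never
re-optimized on test data.

## Group statistics

Continuous comparisons follow the clinical-table dispatch: Shapiro-Wilk
per group and Levene's test (absolute deviations from the group mean),
both at α = 0.05; pass ⇒ pooled t-test with mean ± SD summaries, fail ⇒
Mann-Whitney U (normal approximation, no continuity correction — so
identical groups give exactly p = 1) with median (IQR) summaries. The
dispatch's type-I error is verified to stay within [0.03, 0.07] at the
nominal 0.05 over 2000 null replicates.

Categorical 2×2 tables use Pearson's chi-square without continuity
correction when every expected *and observed* cell is ≥ 5, Fisher's
exact test otherwise; non-2×2 tables switch to Fisher when any expected
count is < 5. The observed-cell trigger is deliberate: on the published
Ki-67 table (44/4 vs 40/14) all expected counts exceed 5, yet only
Fisher's exact test (p = 0.035) reproduces the published p = 0.04 —
uncorrected chi-square gives 0.020 — and the published footnote confirms
Fisher was used. Expected-count-only dispatch would misreproduce that
row.

## Known limitations

* Single-slice 2D analysis only; no 3D texture, no DICOM ingestion, no
  registration.
* The DWT boundary handling (symmetric extension, correlation-form
  filtering) is one documented convention; subband statistics are not
  comparable across implementations with different phase conventions.
* DeLong CIs are Wald-type and clipped to [0, 1]; exact binomial CIs
  are not implemented.
* The synthetic generator is a statistical caricature: no
  pharmacokinetic (Tofts) modeling, no anatomy, and class priors chosen
  for qualitative directionality, not quantitative fidelity to any
  patient cohort.
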