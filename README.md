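# kinetexture

Texture analysis of semiquantitative kinetic parameter maps from breast
DCE-MRI, for predicting HER2 status.

HER2 amplification defines a trastuzumab-treatable breast-cancer subtype,
currently determined by invasive IHC/FISH pathology. Dynamic
contrast-enhanced MRI (one precontrast scan plus eight postcontrast
phases) captures each tumor's enhancement kinetics noninvasively; the
hypothesis implemented here is that the *spatial texture* of per-pixel
kinetic parameter maps carries a HER2 signal that whole-lesion averages
miss. This package is an end-to-end, tested R implementation of that
analysis for radiomics researchers: lesion segmentation, kinetic mapping,
texture extraction, feature selection, logistic modeling, and ROC
evaluation, exercised on a built-in synthetic cohort generator so the
whole pipeline runs without patient data.

## Method

With `s_t` the pixel's signal at phase `t` (t = 0 precontrast) and
`s_peak = max(s_1..s_8)`, seven semiquantitative kinetic parameters are
computed per lesion pixel:

| map | definition |
|---|---|
| E_initial | (s1 − s0) / s0 × 100% |
| E_peak | (s_peak − s0) / s0 × 100% |
| ESER | (s1 − s0) / (s2 − s0) × 100% |
| MSI | max over i of (s_{i+1} − s_i) |
| SEP | (s2 − s0) / s0 × 100% |
| SER | (s_peak − s0) / (s8 − s0) × 100% |
| SI_slope | (s8 − s_mean) / s_mean × 100%, s_mean = (s1 + s2)/2 |

The lesion is delineated on the third-phase subtraction image (Otsu
threshold, largest 8-connected component, hole filling). From each map,
55 texture features are extracted: 4 histogram moments, 19 GLCM
(Haralick) features averaged over four distance-1 offsets, 11 gray-level
run-length features averaged over four angles, and 21 two-level DWT
subband statistics (haar, db2, sym4). Per map, modeling proceeds as:
Pearson correlation filter at |r| > 0.95 → 10-fold cross-validated LASSO
(features with nonzero coefficients at the deviance-minimizing penalty)
→ forward stepwise logistic regression (likelihood-ratio entry/removal
at p = 0.05/0.10) → linear score `Y = β0 + Σ βi·xi`, thresholded at the
training-set Youden optimum and evaluated on the held-out test set at
that frozen threshold (AUC with DeLong 95% CI, sensitivity, specificity,
accuracy).

## Worked example

```r
library(kinetexture)

cs <- generate_case(label = 1, seed = 7)   # synthetic HER2-positive case
pc <- process_case(cs)                     # segment + maps + 7 x 55 features
sum(pc$mask$mask)                          # 234-pixel lesion
round(lesion_means(pc$maps), 2)
#> E_initial    E_peak      ESER       MSI       SEP       SER  SI_slope
#>    144.65    144.65    117.27    172.63    122.60    557.24    -44.11
round(pc$features["ESER", c("hist_Mean", "glcm_Contrast",
                            "grlm_ShortRunEmphasis")], 3)
#>  hist_Mean  glcm_Contrast  grlm_ShortRunEmphasis
#>    117.270          2.988                  0.809
```

The washout kinetics show up directly: SER far above 100% (signal falls
after the early peak) and a negative SI_slope, versus ≈100% and positive
for a persistent enhancer. On the default 48/54 cohort the ESER-map
Short Run Emphasis is lower in the positive class (median 0.79 vs 0.86,
Mann-Whitney p ≈ 2e-14, r_s = −0.76), matching the direction reported
for real tumors.

The full analysis is scripted:

```sh
Rscript analysis/01_simulate.R          # cohort + manifest
Rscript analysis/02_segment_and_maps.R  # Dice vs truth, lesion-mean table
Rscript analysis/03_texture_features.R  # 7 x (102 x 55) feature tables
Rscript analysis/04_model.R             # per-map models + ROC summary
```

Stage 4 prints per-map models such as `ESER: Y = -92.666 + 0.990*hist_Mean`
and a performance table (training AUC ≥ 0.99 on every map for the default
synthetic cohort; the synthetic classes are deliberately well separated).
Outputs land under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete pipeline from scratch against the installed package
(default 48/54 cohort, stratified 72/30 split, per-map selection +
modeling + frozen-threshold test evaluation) and writes the acceptance
JSON to `--out`, logging the best map and its training/test AUC along
the way.
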