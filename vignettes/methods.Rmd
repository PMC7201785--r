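---
title: "Methods: tongue thermography analysis for diabetes prescreening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tongue thermography analysis for diabetes prescreening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguetherm)
```

## The problem and the pipeline

Surface temperature of the extended tongue, imaged with an infrared camera
and rendered as a false-color thermogram, carries a signal about glycaemic
state: diabetic tongues run warmer at the centre ROI, lack cold spots, and
their ROI temperature correlates with HbA1c. The analysis chain implemented
here goes: thermogram → resize to 256×256 → Gaussian smoothing → RGB
color-component thresholding → red (hot-spot) component to grayscale →
fixed centre ROI → GLCM texture features → group statistics and
classification (linear SVM, Gaussian naive Bayes, a small VGG-style CNN)
under stratified 10-fold cross-validation → per-subject CAD report.

Because the original clinical images are restricted, the package includes a
first-class synthetic generator whose defaults encode the published study
conditions. Everything downstream is tested against that generator plus
independent brute-force oracles.

## The cohort model

Subject records are drawn from a **Gaussian copula**: the published
correlation matrix over nine variables (age, hip, waist, DBP, HbA1c, FBS,
PPBS, EAG, tongue-surface temperature) is factored by Cholesky after a
nearest-positive-definite repair; correlated standard normals are scaled to
the published per-group means and SDs; the six remaining variables (height,
weight, BMI, SpO2, core temperature, SBP) are drawn independently. A
Gaussian copula is the simplest joint model consistent with the two pieces
of published information — marginal moments and pairwise correlations — and
with normal margins it preserves the configured Pearson correlations
exactly.

Two published facts force explicit choices:

* **The correlation matrix as printed is indefinite** (smallest eigenvalue
  −0.123). `nearest_pd()` clips eigenvalues at a small floor and rescales
  to a unit diagonal; the key HbA1c–temperature entry moves only from
  0.662 to 0.6619, and no entry moves by more than 0.078. The printed
  table's header row and row labels also disagree about whether SBP or
  waist circumference is present; the row labels are taken as
  authoritative.
* **The pooled-cohort association (r² = 0.5688) and the diabetic-only
  correlation (r = 0.662) are mutually inconsistent**: with the published
  group margins, the between-group mean separation caps the pooled r² near
  0.33 for any within-group correlation ≤ 1. The generator therefore
  exposes both configurations — the default group-wise copula, and a
  pooled mode (`pooled_hba1c_tst_r`) that draws the (HbA1c, temperature)
  pair for the whole cohort from the pooled-mixture mean/SD at a configured
  correlation. Reproducing the scatter-fit r² uses the pooled mode; nothing
  reconciles the two published numbers, and the package does not try.

Physically impossible draws are clipped (SpO2 ≤ 100%, temperatures in
20–42 °C, non-negative anthropometrics); at the default parameters the
clipping binds so rarely that marginal means shift by far less than one
standard error. An optional `consistent_labels` flag clips HbA1c to the
diagnostic rule (diabetic iff HbA1c ≥ 6.5%); it is off by default because
about 18% of the diabetic HbA1c mass lies below 6.5, so enforcing the rule
shifts that margin by ≈ +0.23 (about 0.8 standard errors at n = 70).

BMI is drawn as its own variable rather than computed from height and
weight: only its marginal moments are published, and the three variables'
joint structure is not.

## The temperature-field generator

A field is an elliptical tongue (default axes 0.70 × 0.76 of the frame) on
a 22.5 °C ambient background. Inside the tongue: the subject's recorded ROI
temperature as base level, a smooth quadratic drop of 0.8 °C toward the
rim, group-specific Gaussian spots, and pixel noise (SD 0.15 °C). Finally
the whole tongue is shifted so the mean over the centre ROI (40 × 48 px at
256 × 256, the stand-in for the physical 10 × 12 mm area tool; scaled with
the frame) equals the record's temperature *exactly* — the measured value
is the recorded value by construction, which is what the downstream
statistics assume.

Spot amplitudes are calibrated jointly with the rendering scale and the
published component thresholds, because the three only make sense together:

* under the fixed 28–38 °C scale, a pixel renders into the *blue* component
  band only ≈ 5 °C below tongue base, and into the *red* band ≈ 1.5 °C
  above it;
* the centre-ROI renormalization partly cancels any spot placed on the ROI.

The normal preset therefore uses two deep cold spots (−7 °C, σ = 0.05 of
the frame) and three mild scattered warm spots (+1 °C, σ = 0.06), placed in
an annulus (0.35–0.7 of the ellipse radius) that avoids both the rim and
the pinned centre ROI, at least 2σ apart so amplitudes do not stack. The
diabetic preset uses a single compact, intense centre spot (+2.5 °C,
σ = 0.035) and no cold spots. These defaults reproduce the reported
morphology once rendered: diabetic tongues show a red hot-spot component at
the centre and essentially no blue inside the tongue; normal tongues show
blue cold spots, and their red component is small (often empty), triggering
the documented whole-tongue grayscale fallback. A mild side effect of
subject-level temperature variation is that unusually warm normal tongues
can still render some red — group contrasts hold on average, not per
subject.

"Inside the tongue" for component-fraction measurements means the ellipse
shrunk to 90% of its axes: smoothing mixes tongue and background colors in
a 1–2 px boundary band, and fractions are meant to describe the tongue
surface, not the rendering boundary.

## Palette and inversion

The default palette is a 256-entry HSV sweep from hue 240° (blue) to 0°
(red) at saturation 0.96 and value 252/255, with a fixed 28–38 °C scale.
The slight desaturation is deliberate: a fully saturated sweep emits
channel values 0 and 255, which can never satisfy the published component
bounds (red row maximum 252, green row minima 8 and 6) — the original
palette and thresholds were evidently calibrated together, and this
stand-in must be too. Rendering clamps to the scale and bins linearly into
256 levels; inversion maps each pixel to the temperature midpoint of the
nearest palette entry (Euclidean RGB), giving a round-trip error of at most
half a quantization step, (t_max − t_min)/512 ≈ 0.02 °C. Adjacent palette
entries differ by only ≈ 5 8-bit units along the sweep, so inversion is
exact-bin under ±1 channel noise and within one bin under ±4.

## Segmentation and texture

Component membership is the inclusive triple-interval test per the
published bounds; masks are computed independently and may overlap (the
published green row's R range overlaps the red row's; no exclusivity rule
is published). Grayscale conversion uses the standard Rec. 601 luminance
weights. The centre ROI sits on the tongue-mask centroid (pixels whose
inverted temperature is ≥ 30 °C), with ties rounded toward the top-left and
an image-centre fallback for an empty mask. If the red component is empty
over the ROI, the chain falls back to whole-tongue grayscale with a
classed warning — otherwise half the cohort would have undefined texture.

The GLCM defaults to 8 gray levels (uniform binning of 0–255), offset
(0, 1), symmetric, normalized — the most common co-occurrence convention;
all are configurable. Feature formulas follow the printed definitions,
with three documented numerical choices:

* **Entropy**: the printed form Σ −ln P diverges whenever any cell is
  zero. The default is the standard Shannon entropy −Σ P ln P over nonzero
  cells; `literal_entropy = TRUE` applies the printed form over nonzero
  cells only. Relatedly, the published feature table's entropy (~41–46)
  and kurtosis (~0.01–0.02) magnitudes are not reproducible under any
  standard normalization of these formulas; the package follows the
  formulas and does not reverse-engineer an unstated scaling.
* **Skewness/kurtosis** use population moments (divide by n; σ from the
  population variance; no excess-kurtosis subtraction), exactly as printed.
* **Degenerate ROIs**: a constant ROI yields contrast 0, energy 1,
  homogeneity 1, variance 0, and flagged `NA` for correlation, skewness and
  kurtosis — never silent zeros. For classifier input,
  `impute_undefined_features()` replaces those flagged values by explicit
  neutral constants (correlation 0; skewness 0; kurtosis 3, the Gaussian
  reference), since a quantized single-level ROI genuinely carries no such
  information.

## Statistics

"Student's t-test" is the equal-variance pooled test (the default labelling
of standard statistical software), with Welch behind a flag;
Kruskal–Wallis is tie-corrected with the chi-square approximation and, with
two groups, is equivalent to a Mann–Whitney test; correlation p values are
t-based and two-sided. Raw p values are reported by default (as in the
source analysis); Bonferroni/BH adjustments are available but off. At n = 8
the Kruskal–Wallis chi-square p is a visibly rough approximation (deviating
from the exact permutation p by up to ~0.12); the test suite therefore
checks the H statistic against an exhaustive permutation oracle and the
monotone agreement of the two p values, not their numeric equality.

## Classification

The tabular classifiers consume body circumferences, blood pressure, the
measured ROI temperature and the ten texture features. Unprinted
hyperparameters take conventional defaults: SVM soft-margin C = 1 with
z-scoring fitted inside each training fold; naive Bayes variance smoothing
ε = 1e−9 × the largest feature variance. Cross-validation is stratified,
seeded, and pools held-out predictions into one confusion matrix (the
pooled-CV reading of a single published confusion matrix per classifier;
a hold-out split is available by composing the functions directly).
Screening percentages are truncated — not rounded — to two decimals,
which is the only convention that reproduces the printed values (130/140 →
92.85); half-up rounding is a config option.

The CNN is a down-scaled VGG-style network: blocks of 3×3 convolutions
(He-initialized, ReLU) closed by 2×2 max pooling, a dense ReLU layer and a
softmax head, trained with plain SGD at the published 0.01 learning rate.
Inputs are scaled to [0, 1] and centred at zero (plain SGD conditions far
better on centred inputs). Augmentation (shear, zoom, rotation, horizontal
flip, translation via one inverse-mapped bilinear affine warp) applies to
training images only, re-drawn each epoch. Backpropagation is im2col-based
and verified against numerical differentiation to ~1e−9 relative error.
Full-scale VGG16 with pretrained ImageNet weights is out of scope: no
weights ship with the package, and the `pretrained` flag errors
informatively. Max-pooling gradient ties route to the first matching cell;
fold assignment ties and ROC ties are handled by seeded shuffling and
trapezoidal averaging respectively.

## What the generator does and does not emulate

It reproduces: the published group margins and diabetic-group correlation
structure; the HbA1c labelling rule (optionally); the group morphology
(centre heat concentration and absent cold spots in diabetics, diffuse
patterns with cold spots in normals); a constant rendering scale; and the
ambient 22–23 °C background. It does **not** emulate camera optics or noise
spectra, anatomically realistic tongue shapes, emissivity or atmospheric
effects, longitudinal progression, or the real texture-feature group gaps
(texture differences emerge indirectly from the morphology presets and
differ in magnitude from the published feature table — e.g. the direction
of the GLCM-SD gap is reproduced, its size is not). Passing tests
demonstrate that the *method* is implemented correctly and behaves as
reported under the published study conditions; they say nothing about
classifier accuracy on real clinical thermograms, and the published
real-data accuracies (92.85% SVM, 89.28% NB, 94.28% CNN) are deliberately
not claimed as reproducible. One further published quantity is left as
found: the stated 2.35% group temperature difference does not follow from
the published group means (0.61 °C on ≈ 34.9 °C ≈ 1.8%); the generator
targets the means.

## Problem sizes

The test suite exercises the generator at n = 70 per group (100 seeds for
marginal recovery, 200 for the correlation target), the GLCM oracle on 100
random 8×8 images, the t-test calibration on 5,000 null replicates, the
full image pipeline on one 140-subject study at 256×256, and the CNN on 40
synthetic 48×48 thermograms for 15 epochs; the acceptance script uses 100
seeds of 140-subject cohorts and 100 × 70 rendered 96×96 fields. These
sizes were chosen so the whole suite runs in a few minutes on one CPU while
keeping every stochastic check several standard errors away from its
threshold.

## Known limitations

* The rainbow palette is a documented stand-in, not the proprietary camera
  palette; inversion of real images rendered under other palettes requires
  supplying that palette.
* The physical pixel pitch of the acquisition is unpublished, so the
  10 × 12 mm ROI cannot be converted to pixels exactly; 40 × 48 px at
  256 × 256 is an explicit configurable default (`mm_per_pixel` is honoured
  when known).
* Component masks are non-exclusive; visualization precedence (red > green
  > blue) is a display choice only.
* The optional "white" component rule (all channels ≥ 240) is an
  extrapolation beyond the published threshold table and is off by default.
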