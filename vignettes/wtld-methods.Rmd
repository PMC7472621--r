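---
title: "Weber texture coding for individual animal identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weber texture coding for individual animal identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Group-housed livestock (the motivating case is pigs imaged top-down in a pen)
must be told apart without tags or fixed postures. The usable signal is the
back texture: hair growth direction, skin lines, and coat spots differ between
individuals and persist over time. This package implements a handcrafted local
texture descriptor — the Weber texture local descriptor (WTLD) — that encodes
exactly those cues, plus the classical Weber local descriptor (WLD) as the
baseline it improves on, a block-histogram feature builder, and an SVM
cross-validation harness. Because no field imagery ships with the package, a
seeded synthetic texture generator instantiates the same cue families so every
stage is testable end to end.

## The descriptor

All computation happens on 8-bit grayscale rasters (matrices, 0–255). Colour
inputs are converted with BT.601 luma and images are resized to a working
resolution of 100×100 by bilinear interpolation.

**Differential excitation.** For a pixel $x_c$ with 8-neighbourhood
$x_0,\dots,x_7$,
$$\gamma(x_c) = \arctan\!\Big[\sum_{i=0}^{7}\frac{x_i - x_c}{x_c + \epsilon}\Big],$$
a Weber-law measure of local salience: the perceptible change relative to the
background level. The guard $\epsilon = 10^{-6}$ keeps $x_c = 0$ finite and is
negligible against the smallest positive 8-bit intensity; $\gamma$ is then
invariant (to ~$10^{-6}$ relative) under multiplicative illumination scaling.
$\gamma \in (-\pi/2, \pi/2)$ is divided into $M$ equal bands and each band
into $S$ intervals, giving $M\!\cdot\!S$ uniform bins. Defaults $M=6$, $S=5$:
coarse frequency bands with fine intervals inside each.

**Directional filtering.** The image is correlated with a compass bank of 8
kernels $M_i$ and absolute responses taken: $R_i = |I \ast M_i|$. Direction
indices are fixed package-wide: 0 = east, counter-clockwise in 45° steps, the
same indexing for kernels and for the 8-neighbourhood, so index $i$ and index
$(i+4) \bmod 8$ are geometrically opposite. Kirsch 3×3 is the default family;
Sobel and Prewitt banks and sizes 5/7/9 are available. Sizes above 3 use the
standard compass construction (separable derivative kernels on the axes,
ring-wise 45° coefficient rotation for diagonals; the Kirsch +5/−3 arc pattern
ring-extended with 3r fives per ring of radius r, which keeps every kernel
zero-sum). The exact extended coefficients can be dumped with
`write_mask_bank_csv()` for inspection or substitution.

**Main directions and structure code.** Per pixel, $D_1,\dots,D_4$ are the
indices of the four largest responses (ties resolved toward the smaller index,
so the coding is fully deterministic). For each main direction the signed
difference between the neighbour in that direction and the opposite neighbour
is taken:
$$C_i = N_{D_i} - N_{(D_i+4) \bmod 8},$$
then binarized by an adaptive per-pixel threshold
$$\sigma = \tfrac14\sum_{i=1}^{4}|C_i|, \qquad
  M_i = \mathbb{1}\{|C_i| > \sigma\},$$
and the final 4-bit code is $L = 2 D_1 + M_1 \in \{0,\dots,15\}$: the dominant
orientation plus one bit saying whether the intensity step across that
orientation is above the local average. A variant threshold
(`sigma_rule = "over_n_minus_1"`) averages only the three strongest
differences ($\div 3$); the two rules coincide whenever the four magnitudes
are equal, and both are exposed because the threshold's printed definitions in
the literature are ambiguous between them. Only $D_1$ and $M_1$ enter the
default code; an optional two-direction code $4D_1 + 2M_1 + M_2$ (32 bins) is
available through `structure_code(..., M2 =)`.

**Feature vector.** The descriptor cascades (a) the global joint histogram of
($D_1$, excitation bin), $8 \times (6\cdot 5) = 240$ cells, with (b) a 16-bin
histogram of $L$ on each cell of a 4×4 sub-block grid, $16 \times 16 = 256$
values. Total length 496 from 256 distinct histogram cells. The joint
histogram is global and only the structure codes are sub-blocked — this is
forced by the published dimension accounting (the 240-cell term appears once,
the 16-bin term sixteen times). Each segment is L1-normalized by default;
histograms at different image sizes are then comparable under an SVM, and raw
counts remain available (`normalization = "none"`).

The baseline WLD uses the same excitation plus a gradient orientation
$\theta = \operatorname{atan2}(g_v, g_h)$ from opposite 4-neighbour
differences, quantized into $T = 8$ bins (zero gradient → bin 0 by
convention). Its `"table5"` preset (T=8, M=4, S=1 per block, 4×4 grid, 512
values) reproduces the published comparison dimensions; the exact
sub-quantization behind those dimensions is not recoverable from the
literature, so the preset fixes the dimension, not necessarily the original
binning. The `"classic"` preset gives the textbook global 240-bin histogram.

## Numerical choices

* **Exact integer convolution.** Mask responses are computed by
  shift-and-add correlation rather than FFT. On integer images with integer
  kernels every response is exact, which makes the argmax and its
  deterministic tie-break reproducible bit for bit against a naive per-pixel
  reference — the property the test suite asserts on 100 random images.
* **Replicate padding** everywhere (mask responses and neighbour lookups), so
  every raster keeps the image size and border pixels are defined.
* **Correlation, not flipped convolution.** Since the bank contains all eight
  rotations, flipping would only relabel directions; the unflipped convention
  is fixed and documented.
* **Ties.** Constant regions give all-zero responses; the smallest-index rule
  then yields $D_{1..4} = 0,1,2,3$. One consequence: the covariance
  "rotate the image 90° ⇒ interior $D_1$ advances by 2 (mod 8)" holds exactly
  at pixels whose maximum response is unique, while at exact ties the index
  rule, not geometry, decides. Tests assert the covariance on the
  unique-argmax pixels (typically >90% of a random image).
* **Strict binarization.** $|C_i| = \sigma$ codes as 0, so flat pixels code
  as all-zero bits, and the threshold's degree-1 homogeneity makes the code
  raster exactly invariant under intensity scaling $k \in \{0.5, 2, 3\}$
  (tested as such).

## Evaluation protocol

`crossval_evaluate()` reproduces the standard protocol: stratified five-fold
cross-validation (stratification guarantees every class in every training
split at small n; plain random splitting does not), an SVM with linear,
third-order polynomial, or RBF kernel, and $C = 100$ for RBF ($C = 1$
otherwise, overridable). Per-fold test accuracies are averaged for the
headline accuracy; precision, specificity and F1 are computed one-vs-rest per
class from the confusion matrix pooled over the five folds and macro-averaged
(micro averaging is a flag; which averaging the published tables used is not
stated, so the choice is documented rather than asserted). Features enter the
SVM unscaled because the histogram segments are already L1-normalized;
libsvm's default RBF/polynomial `gamma = 1/d` and `coef0 = 0` apply.
`tidy()`, `glance()` and `autoplot()` give per-class metrics, a one-row
summary, and a confusion heat map.

## What the synthetic data does and does not show

`generate_dataset()` draws, per class: a base coat intensity, an oriented
sinusoid (hair stripe direction/spacing/contrast; random phase per image),
Poisson-many elliptical spots at random positions/orientations, a
random-direction linear illumination gradient, and i.i.d. Gaussian noise,
clipped and rounded to 8 bits. Defaults are chosen to emulate a moderately
hard 10-individual herd: stripe angles evenly spaced over 180° (so no two
classes share an orientation), frequencies cycling 6/9/12/15 cycles per
image-width, contrast 25 against noise sd 10, 2–5 spots of ±40 intensity, and
base intensities cycling 100–140. With 50 images per class this mimics the
scale of a 500-image field dataset.

These textures are stationary, perfectly segmented, and driven by exactly the
cues the descriptor measures. Passing the evaluation on them demonstrates
that the pipeline is implemented correctly and that the descriptor separates
orientation/spot/intensity differences under noise and illumination drift —
it does not demonstrate field performance on real animals, where posture,
occlusion, segmentation error and non-stationary textures intervene (the
`degrade()` operator applies rotations, rescalings and occluding bars to probe
those failure modes). Published accuracies on proprietary farm datasets are
therefore not reproduction targets for this package.

Problem sizes used by the test suite and the acceptance script — 16×16 rasters
for the bit-exactness oracle (100 seeds), 100×100 rasters elsewhere, and the
500-image default dataset for the classification checks — were chosen as the
smallest sizes at which every property is non-trivially exercised.

## Known limitations

* Extended (5/7/9) mask coefficients follow the documented compass
  construction; other implementations may use different extended grids, so
  cross-implementation comparisons at those sizes need the CSV dump.
* The descriptor is not rotation-invariant by design (rotation permutes the
  code alphabet); identification across arbitrary postures relies on the
  classifier having seen varied postures.
* Single scale only: no multi-radius excitation or filter pyramid.
* `wld_orientation()`'s bin edges at exact 45° multiples are subject to
  floating-point rounding of `atan2`; bins are deterministic but edge pixels
  may not shift exactly by $T/4$ under rotation.
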