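# wtld

Texture-based identification of individual animals from top-view grayscale
images, built around the **Weber texture local descriptor (WTLD)**. The
package is aimed at researchers in precision livestock farming and biological
image analysis who need a compact, handcrafted descriptor that separates
individuals by the texture of their backs — hair growth direction, skin
lines, coat spots — without tags, fixed postures, or deep networks.

## The method

For every pixel $x_c$ with 8-neighbourhood $x_0,\dots,x_7$ the descriptor
computes:

1. **Differential excitation**
   $\gamma(x_c) = \arctan\big[\sum_{i=0}^{7}(x_i - x_c)/(x_c+\epsilon)\big]$,
   a Weber-law salience measure, quantized into $M\times S$ uniform bins
   (defaults $M=6$, $S=5$).
2. **Directional responses** $R_i = |I * M_i|$ against an 8-direction compass
   mask bank (Kirsch 3×3 by default; Sobel/Prewitt and sizes 5/7/9
   available), and the **main directions** $D_1,\dots,D_4$ — the indices of
   the four largest responses.
3. **Main-direction intensity differences**
   $C_i = N_{D_i} - N_{(D_i+4)\bmod 8}$ between opposite neighbours,
   binarized by the adaptive per-pixel threshold
   $\sigma = \frac{1}{4}\sum_{i=1}^{4}|C_i|$ as
   $M_i = \mathbb{1}\{|C_i|>\sigma\}$.
4. The **structure code** $L = 2D_1 + M_1 \in \{0,\dots,15\}$.

The feature vector cascades the global $8\times(6\cdot5) = 240$-cell joint
(direction, excitation) histogram with 16-bin histograms of $L$ on a 4×4
sub-block grid: $240 + 256 = 496$ values from 256 distinct histogram cells.
The baseline WLD (excitation + gradient orientation only) is included for
comparison, and a stratified five-fold SVM harness (linear / 3rd-order
polynomial / RBF with $C = 100$) reports accuracy, macro precision,
specificity, F1 and confusion matrices. A seeded synthetic generator produces
labelled back-texture images (oriented stripes, elliptical spots,
illumination gradients, sensor noise) so the whole pipeline runs without
field data.

## Worked example

```r
library(wtld)

ds <- generate_dataset(synth_config(n_classes = 10, images_per_class = 50,
                                    noise_sd = 10, seed = 7))
features <- extract_features(ds, descriptor = "wtld")   # 500 x 496 + id cols
ev <- crossval_evaluate(features, kernel = "rbf", C = 100, seed = 42)
ev
#> <wtld_eval> rbf kernel SVM (C = 100), 5-fold stratified CV, n = 500
#>   fold accuracies: 1.000 1.000 1.000 1.000 1.000
#>   mean accuracy 1.000 | precision 1.000 | specificity 1.000 | F1 1.000 (macro)

glance(ev)
#> # A tibble: 1 × 9
#>   kernel     C mean_accuracy sd_accuracy precision specificity    f1     n  seed
#>   <chr>  <dbl>         <dbl>       <dbl>     <dbl>       <dbl> <dbl> <int> <int>
#> 1 rbf      100             1           0         1           1     1   500    42
```

The ten synthetic individuals differ in stripe orientation, stripe frequency,
spot pattern and base coat intensity; at noise sd 10 the WTLD features
separate them perfectly (a raw-pixel baseline under the identical SVM reaches
about 0.81, and permuting the labels collapses accuracy to chance, ~0.10).
`tidy(ev)` gives per-class precision/recall/specificity/F1 and
`autoplot(ev)` draws the pooled confusion matrix.

Pixel-level rasters are available for inspection:

```r
pm <- wtld_pixel_maps(ds$image[[1]])   # gamma, R, D, C, Mbits, L
length(wtld_feature(ds$image[[1]]))
#> [1] 496
```

A thin command-line interface chains the stages
(`synth → extract → train-eval`, plus `masks` to dump kernel banks):

```sh
Rscript inst/cli/wtld synth --out imgs/ --classes 10 --per-class 50 --seed 7
Rscript inst/cli/wtld extract --images imgs/ --out features.csv
Rscript inst/cli/wtld train-eval --features features.csv --kernel rbf --C 100 \
    --seed 42 --report report.json
```

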