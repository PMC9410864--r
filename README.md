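# dpcseg

Microfeature segmentation of biological images by improved density-peak
clustering.

Noisy biological images — cell cultures, tissue fields, microscopy frames —
contain many small features of similar appearance on a cluttered background.
`dpcseg` segments such images without training data by compressing the image
into superpixels and clustering those superpixels by density peaks in a joint
color–space feature domain. It is aimed at image-analysis practitioners who
need a deterministic, parameter-light segmenter plus the matching evaluation
metrics (integrity rate, noise variance, missing features, accuracy) and a
ground-truthed phantom generator for validation.

## Method

The pipeline has four stages:

1. **Feature space.** The image is converted to CIELAB (gray images embed as
   `l = gray, a = b = 0`) and compressed into SLIC-style superpixels with the
   joint distance

   ```
   D_s = d_lab + (m / S) * d_xy
   ```

   where `d_lab` and `d_xy` are Euclidean color and pixel distances, `S` is
   the superpixel grid spacing and `m` the compactness index. Each
   superpixel becomes one point `(x, y, l, a, b)` — centroid over `h_s`,
   mean color over `h_r` — weighted by its pixel count `P_i`.

2. **Density-peak clustering.** For each point, a local density

   ```
   rho_i = sum over { j : d_ij <= d_c } of P_j     (weighted cutoff kernel)
   ```

   and a separation `delta_i` = distance to the nearest point of higher
   density (the global density peak takes `max_j d_ij`). Cluster centers are
   the `k` points with the largest decision score `gamma_i = rho_i *
   delta_i`, optionally weighted by the gray-level Shannon entropy `H_i` of
   each superpixel's pixels; all other points inherit the label of their
   nearest higher-density neighbour, in descending-density order. `d_c` is
   constrained to (0, 10] and `k` to [2, 30]; both are chosen automatically
   by default (distance quantile, largest score gap).

3. **Noise isolation.** Each pixel is summarized by the mean feature of its
   8-neighbourhood; pixels whose variance-weighted distance
   `sqrt(sum_f W_f (xbar_i,f - mu_r,f)^2)` to their own region is anomalous
   are reassigned to the nearest region.

4. **Evaluation.** Integrity rate `R = chi'/chi * 100%` (share of
   ground-truth features completely segmented, IoU >= 0.7 by default),
   block-variance noise estimation (mean of the lowest 1% of tile
   variances), missing-feature count, adjusted Rand index and per-feature
   IoU.

## Worked example

```r
library(dpcseg)

# a 256x256 phantom: 10 elliptical cells on gray-64 background, sigma = 10
ph  <- generate_phantom(phantom_spec(size = 256, n_features = 10,
                                     noise_sigma = 10, seed = 42))
res <- segment_image(ph$image)
res
#> <segmentation_result 256 x 256, k=2 clusters, K=204 superpixels>

evaluate_segmentation(res$labels, ph$truth, raster = ph$image)
#> <evaluation_report R=100.0% (10/10), missing=0, ARI=0.952, mean IoU=0.978, noise var=91.6>
```

Reading the output: the 256x256 phantom was compressed to 204 superpixels
and clustered into `k = 2` pixel classes (features vs. background). All 10
planted cells were completely segmented (`R = 100%`, no missing features);
the pixel partition agrees with the truth at ARI 0.952 and the matched
per-feature IoU averages 0.978. The block-variance estimate of the additive
noise, 91.6, recovers the planted variance `sigma^2 = 100` within its
expected low bias.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dpcseg.R", package = "dpcseg"))')
Rscript $CLI simulate --size 256 --n-features 10 --noise-sigma 10 \
        --seed 42 --out img.png --truth truth.png
Rscript $CLI segment img.png --out labels.png --manifest manifest.json
Rscript $CLI evaluate labels.png truth.png --image img.png --report report.json
```

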