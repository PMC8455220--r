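# fuzzyseg

Noise-robust fuzzy c-means segmentation of grayscale images with
guided-filter membership regularization and morphological reconstruction.

## The problem

Fuzzy c-means (FCM) partitions the pixels of an image into C clusters by
minimizing

    J(U, V) = Σ_c Σ_n u_cn^m ‖x_n − v_c‖²,    subject to Σ_c u_cn = 1,

alternating the closed-form updates

    u_cn = 1 / Σ_j (‖x_n − v_c‖ / ‖x_n − v_j‖)^(2/(m−1)),
    v_c  = Σ_n u_cn^m x_n / Σ_n u_cn^m ,

until the objective stabilizes.  Because each pixel is clustered by its
intensity alone, FCM degrades badly on noisy images — the typical setting
for biological imagery such as brain MRI, where Gaussian, impulse
(salt & pepper) and Rician noise are all common.

`fuzzyseg` implements a family of remedies around a single Picard
iteration engine:

* **FCM_S1 / FCM_S2** — the classical spatially constrained baselines:
  the objective gains a neighbor term `α‖x̄_n − v_c‖²` with `x̄` a
  precomputed 3×3 window mean (S1) or median (S2).
* **FCM+GF** — after every membership update, each cluster's membership
  map is smoothed by a **guided filter** whose guidance is the raw noisy
  image itself, so smoothing stops at image edges.  The filter fits, per
  window ω_k, a ridge-regularized linear model q = a_k I + b_k with

      a_k = (mean(I·p) − μ_k p̄_k) / (σ_k² + ε),    b_k = p̄_k − a_k μ_k,

  and averages the coefficients over all windows covering a pixel.
* **IFCM_GF** — the guidance image is scaled by an *influence factor* ρ
  before filtering.  Scaling the guidance by ρ is algebraically identical
  to replacing ε by ε/ρ², so one scalar adapts the filter's
  flat-patch/edge discrimination to the noise level (small ρ ⇒ strong
  smoothing).  The package verifies this identity to 1e−8 as a core
  property test.
* **MRIFCM_GF** — before clustering, the noisy image is denoised once by
  grayscale **morphological closing reconstruction** β = R^C(f)
  (geodesic reconstructions with a 3×3 structuring element composed as
  closing-by-reconstruction of the opening-by-reconstruction).  The FCM
  objective runs on β while the guided filter is still guided by ρ·f,
  the raw image.  Reconstruction removes impulse and Gaussian noise
  alike, which makes a single small ρ work across noise levels.

Supporting modules provide the 256×256 ST (3-class: 0/85/170) and SF
(4-class: 0/85/170/255) phantoms with pixel-aligned ground truth,
seeded Gaussian / salt-&-pepper / Rician noise generators, and an
evaluation harness: segmentation accuracy SA = D/N under the optimal
cluster-to-class bijection, averaged over repeated seeded runs (ASA),
plus ρ-sweep curves and benchmark-table reproduction.

## Worked example

```r
library(fuzzyseg)
ph    <- makePhantom("ST")                 # image + ground-truth labels
img   <- normalizeImage(ph$image)          # [0,1] scale
noisy <- addNoise(img, "gaussian", 0.05, seed = 42)   # 5% variance

res <- mrifcmGF(noisy, C = 3, rho = 0.009, seed = 1)
res
#> FuzzySegResult (mrifcm_gf): 256 x 256 image, C=3 clusters
#>   centers: 0.3353, 0.0309, 0.6577
#>   14 iterations, converged: TRUE, final J = 233.866
segmentationAccuracy(segLabels(res), ph$labels)$sa
#> [1] 0.9967957
segmentationAccuracy(segLabels(fcm(noisy, C = 3, seed = 1)), ph$labels)$sa
#> [1] 0.6789703
```

The cluster centers land on the three class intensities
(0, 85, 170)/255 ≈ (0.031, 0.335, 0.658, in the engine's arbitrary
order).  Under 5%-variance Gaussian noise the reconstruction-plus-guided-
filter variant segments 99.7% of pixels correctly where plain FCM
reaches 67.9%.

Averaged accuracy over repeated runs, and the benchmark driver:

```r
runASA("ifcm_gf", "ST", "salt_pepper", 0.10, rho = 0.008, reps = 20)$asa
reproduceTable("T1", reps = 20, out = "t1.csv")
sweepRho("mrifcm_gf", "ST", "gaussian", 0.15,
         rhoGrid = c(0.001, 0.005, 0.01, 0.05), reps = 10)
```

A thin command-line interface wrapping these functions ships in
`inst/scripts/fuzzyseg.R` (subcommands `generate`, `reconstruct`,
`segment`, `sweep`, `reproduce`).

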