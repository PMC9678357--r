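# plastimap

Motor skill learning remodels the brain: longitudinal voxel-based
morphometry (VBM) in trained mice shows gray-matter volume decreasing while
white-matter volume increases in sensorimotor cortex, following distinct
time courses, and histology ties the white-matter signal to intracortical
myelin. `plastimap` implements the computational machinery of such a study
as a tested R package:

* **Voxelwise time-course morphometry** — per-voxel linear mixed models of
  modulated tissue-volume maps over six sessions,

  `y = β₀ + β₁·TIV + β₂·group + β₃·f(t) + β₄·group·f(t) + b₀ᵢ + b₁ᵢ·f(t) + ε`,

  fitted by ML for each of three trajectory bases
  (linear `t/T`; asymptotic `1−(1−t/T)²`; quadratic `4t(T−t)/T²`),
  with Benjamini–Hochberg FDR maps of the group-by-time interaction,
  AIC preferred-model maps (margin ΔAIC > 10), cluster volumes
  (count × 0.08³ mm³), VOI trajectories normalized to controls, and
  per-subject trajectory AICc.
* **Model selection** — small-sample AICc
  (`−2logL + 2k + 2k(k+1)/(n−k−1)`), pairwise Akaike probability
  `e^{0.5D}/(1+e^{0.5D})`, and the ΔAICc > 2 decisiveness rule.
* **3D myelinated-axon reconstruction** — Perona–Malik diffusion + Gaussian
  smoothing, Otsu binarization, topology-preserving 3D thinning to
  centerlines, nodes every 0.5 µm with distance-transform radii,
  labeled-depth screening (per-slice q99 > 75/255, contiguous depth
  Thref > 2 µm), and depth-corrected metrics: length density, mean
  diameter, volumetric fraction over `V = A·(Thref + 0.5 µm)`.
* **Densitometry** — exact three-class multi-Otsu segmentation of
  fluorescence sections; immunoreactivity of the specific class.
* **Behavior** — single-pellet reaching scores (success, pooled-attempt
  accuracy, first-attempt success) and logarithmic learning rates.
* **Synthetic data** — seeded generators for every modality with stored
  ground truth, so the full pipeline runs and is validated with no
  external data.

## Worked example

```r
library(plastimap)

# --- simulate a cohort: 4% asymptotic decrease in a 5^3 block ---------
sim  <- simLongitudinalVolumes(seed = 11, nPerGroup = 8, grid = c(8, 8, 8),
                               effectAmplitude = -0.05)
maps <- voxelwiseMaps(sim$series, array(TRUE, c(8, 8, 8)), q = 0.05)
maps
#> VoxelFitMaps: linear, asymptotic, quadratic on 512 in-mask voxels (q = 0.05 )
#>   linear      sig+ 0, sig- 125 voxels
#>   asymptotic  sig+ 0, sig- 125 voxels
#>   quadratic   sig+ 0, sig- 0 voxels
#>   preferred-model voxels (delta-AIC > 10 ): linear 2, asymptotic 61, quadratic 0
```

All 125 voxels of the implanted effect region are recovered as decreases
(`sig-`), none outside it, and the decisively labeled voxels name the
generating asymptotic shape. Model comparison on printed AICc values:

```r
akaikeProbability(-682.2, -699.8, c("linear", "quadratic"))
#> ModelComparison: preferred 'quadratic' (delta-AICc = 17.6, p = 99.98%, decisive)
```

A full fiber probe, from raw stack to metrics:

```r
fib <- simFiberStack(seed = 1)          # 17x17 um probe, 10 fibers, truth stored
res <- fiberPipeline(fib$stack)
res$metrics
#> FiberMetrics: length density 0.0897 um^-2, mean diameter 0.821 um,
#>   volumetric fraction 0.05333 (Thref 4.80 um, volume 1583 um^3)
c(truth = fib$truth$trueDensity, diameter = 2 * fib$truth$radius)
#>      truth   diameter
#> 0.09307636 0.90000000
```

Length density lands within ~4% of the generative truth and the diameter
within ~9%.

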