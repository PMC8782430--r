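# texkem

Texture-guided kernelized EM reconstruction for dynamic PET, in R.

Dynamic PET follows tracer kinetics by splitting a scan into many short
frames; each frame then holds few counts and frame-by-frame MLEM
reconstructions are very noisy. The kernelized EM (KEM) framework
represents the image as **x = Kα**, where the kernel matrix **K** encodes
similarity between pixels' feature vectors derived from high-count
composite-frame *prior images*, and iterates EM on the coefficients:

    α⁽ⁿ⁺¹⁾ = α⁽ⁿ⁾ / (KᵀPᵀ1) · KᵀPᵀ( y / (PKα⁽ⁿ⁾ + r) ),    x̂ = Kα̂

with **P** the projection operator, **y** the measured sinogram and **r**
the expected background. With **K = I** this is exactly MLEM.

This package implements a *dual-texture* KEM in which the per-pixel feature
vector stacks, for each of three composite-frame MLEM priors, the prior
intensity plus two texture descriptors:

- **IDM** — the inverse difference moment of the gray level-gradient
  co-occurrence matrix (GGCM), Σᵢⱼ P(i,j)/(1+(i−j)²), computed on 5×5
  neighbourhoods;
- **LRLGE** — the long-run low gray-level emphasis of the gray-level run
  length matrix (GLRLM), (1/n_r) Σᵢⱼ p(i,j)·j²/i², averaged over the four
  scan directions, on 3×3 neighbourhoods;

plus a GLCM-correlation feature as a comparator baseline. The kernel is a
sparse Gaussian similarity over the k = 50 nearest feature neighbours in a
9×9 spatial window, row-normalized so constants are preserved.

Around the reconstruction core the package provides the full simulation
study: a 217×217 brain-like digital phantom with a 5-pixel tumor, regional
time-activity curves, a 24-frame / 60-minute schedule, a matched
parallel-beam projector pair (249×210 sinograms) with attenuation, Poisson
noise at a 3×10⁷ count level with 20% uniform background, and the
evaluation metrics SNR, NMSE, SSIM, ROI SD and contrast recovery
coefficient (CRC). It is intended for researchers prototyping
prior-guided / kernel reconstruction methods and for teaching tomographic
reconstruction.

## Worked example

A reduced end-to-end experiment (64×64 phantom, six 100-second frames, two
noise realizations, 10 EM iterations):

```r
library(texkem)
cfg <- experiment_config(
  grid_size = 64, tumor_radius = 3,
  schedule = frame_schedule(rep(100, 6)),
  n_radial = 95, n_angles = 60,
  total_counts = 2e6, realizations = 2,
  k = 10, search_window = 5, iterations = 10, prior_iterations = 25,
  methods = c("mlem", "kem_dual"), seed = 17)
res <- run_experiment(cfg)
aggregate(cbind(nmse, crc, ssim) ~ method, res$metrics, mean)
#>     method       nmse       crc      ssim
#> 1 kem_dual 0.06613651 0.2860247 0.9444159
#> 2     mlem 0.07532111 0.2985739 0.9366095
```

The table averages the per-frame metrics over all frames and realizations:
the texture-kernelized reconstruction has lower normalized mean squared
error and higher structural similarity than plain MLEM at the same
iteration count. CRC (reconstructed tumor contrast over true contrast) is
far below 1 for both methods here because 10 iterations on a tiny phantom
leave the hot tumor unconverged — at the study's full scale (217² phantom,
100 iterations; the `experiment_config()` defaults) CRC approaches 1.
Individual stages are available as plain functions: `brain_phantom()`,
`simulate_acquisition()`, `rebin_composite_frames()`, `make_priors()`,
`feature_image()`, `build_kernel()`, `mlem()`, `kem()`, `metrics_report()`.

A thin command-line interface wrapping the same functions ships in
`inst/cli/texkem.R`:

```sh
Rscript inst/cli/texkem.R run --config experiment.yaml --out results/
Rscript inst/cli/texkem.R features --image img.csv --descriptor lrlge --out map.csv
```

## Layout

- `R/` — phantom & acquisition, projector, texture descriptors, kernel
  builder, MLEM/KEM, metrics, pipeline, I/O
- `src/` — compiled sliding-window texture feature maps
- `vignettes/texkem-methods.Rmd` — the model, parameter meanings, design
  decisions and limitations
- `tests/testthat/` — unit, property and acceptance tests (with
  independent brute-force oracles for every texture descriptor)
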