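# guidefit

Accuracy verification for CT-derived dental guide models against
optical-scan gold standards.

## What problem this solves

Computer-aided implant surgery plans on CT data and transfers the plan to
the patient through a stereolithographic surgical guide. The very first
step of that chain — reconstructing the radiographic template from DICOM
slices by threshold segmentation — already changes the object's size with
the operator's choice of the intensity cutoff τ, because partial-volume
blur makes the boundary intensity transition smooth. `guidefit` is for
clinicians and engineers who verify this chain: it aligns the CT isosurface
to a structured-light optical scan of the same object (an order of
magnitude more accurate than CT) and calibrates τ so the reconstruction
matches the gold standard.

The package provides:

* **Segmentation** — threshold masks (`>=` superlevel sets), 26-connected
  component cleaning, and marching-cubes isosurface extraction in world
  millimetres (`threshold_mask()`, `largest_component()`,
  `extract_isosurface()`).
* **Registration** — closed-form landmark alignment by the SVD method with
  reflection correction (`landmark_register()`), refined by trimmed
  point-to-point iterative closest point with exact point-to-triangle
  correspondences (`icp_refine()`).
* **Deviation analysis** — full-field signed point-to-surface distances
  (positive = test model larger than gold), mating-surface ROIs, mean /
  population-SD / zero-anchored histograms (`signed_distances()`,
  `compare_surfaces()`, `deviation_stats()`).
* **Threshold calibration** — the core operation: find τ* minimising the
  absolute mean signed deviation |d̄(τ)| by grid search plus bisection on
  the sign of d̄(τ), which decreases monotonically in τ
  (`optimize_threshold()`).
* **Synthetic phantom** — a dental-arch analogue (swept tube with
  tooth-like bumps) with CT-like voxelisation, Gaussian partial-volume
  blur, noise, and a noisy optical scan in a known pose, so the entire
  pipeline is verifiable without patient data (`phantom_spec()`,
  `make_phantom_pair()`, `run_phantom_study()`).
* **IO** — DICOM series reading (axial, axis-aligned), NRRD volumes, binary
  STL and ascii PLY meshes, plain-text landmark files, JSON reports and
  PLY deviation maps with a per-vertex `quality` channel.

## Worked example

Calibrate the segmentation threshold of a synthetic CT against its optical
gold standard:

```r
library(guidefit)

spec <- phantom_spec(seed = 1)          # arch phantom, fg 1000 / bg 0
pair <- make_phantom_pair(spec, spacing = 0.3)
pair$ct
#> <voxel_volume> 164 x 211 x 81 voxels, spacing (0.3, 0.3, 0.3) mm, intensity [0, 1000]

# landmark pairs picked on the two models (here: ground truth + 0.1 mm jitter)
lm <- withr::with_seed(4, {
  vi <- sample.int(nrow(pair$mesh$vertices), 6)
  src <- pair$mesh$vertices[vi, ]
  landmark_set(src, apply_transform(src, spec$true_pose) +
                    matrix(rnorm(18, sd = 0.1), 6, 3))
})
init <- landmark_register(lm)

res <- optimize_threshold(pair$ct, pair$optical, bracket = c(200, 800),
                          init = init, icp = icp_params(seed = 3), seed = 9)
res
#> <threshold_result> tau* = 481.25 (|mean| = 0.0021 mm, SD = 0.0409 mm; bisection, 11 evaluations)

for (tau in c(300, res$tau_star, 700)) {
  r <- deviation_objective(pair$ct, tau, pair$optical,
                           fixed_transform = res$transform, seed = 9)
  cat(sprintf("tau = %6.2f: %s\n", tau, format_deviation_stats(r$stats)))
}
#> tau = 300.00: mean value 0.290 mm, SD 0.046 mm
#> tau = 481.25: mean value 0.002 mm, SD 0.041 mm
#> tau = 700.00: mean value -0.343 mm, SD 0.037 mm
```

Reading the output: at a low threshold (300) the reconstruction is ~0.29 mm
*larger* than the optical gold standard (positive mean); at a high
threshold (700) it is ~0.34 mm *smaller*; at the calibrated τ* = 481 the
mean deviation collapses to 2 µm. The optimum sits slightly below the ideal
half level 500 because Gaussian blur shifts the half-level set inward by
roughly σ²·(κ₁+κ₂)/2 on a curved surface (see the vignette).

A command-line interface with the same operations ships in
`inst/cli/guidefit.R` (subcommands `phantom`, `segment`, `register`,
`compare`, `optimize-tau`, `study`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/guidefit.R", package = "guidefit"))')" \
  segment --volume ct.nrrd --tau 500 --keep-largest --out mesh.stl
```

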