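---
title: "Calibrating CT segmentation thresholds against an optical gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating CT segmentation thresholds against an optical gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidefit)
```

## The problem

Image-guided dental implant surgery transfers a plan made on CT data to the
patient through a stereolithographic surgical guide. Every step of that chain
loses accuracy, and the first loss happens before any manufacturing: the 3D
model of the radiographic template is reconstructed from DICOM slices by
*threshold segmentation*, and the operator's choice of the intensity cutoff
$\tau$ directly changes the size of the reconstructed object. Because the
intensity transition across the acrylic-resin boundary is smooth (partial
volume averaging), there is no self-evident "correct" threshold: a low $\tau$
inflates the model, a high $\tau$ shrinks it.

`guidefit` implements a verification workflow built around a structured-light
optical scan of the same physical object. Optical scanners of the class used
for dental models resolve about 0.1 mm spatially with an overall accuracy
near 0.01 mm — roughly an order of magnitude better than CT — so the optical
mesh serves as the gold standard. The CT isosurface is rigidly aligned to it
and the full-field signed deviation is measured; the threshold is then chosen
to null the mean signed deviation.

## Model and procedure

For a CT volume $V$ and threshold $\tau$, marching cubes extracts the
isosurface $S(\tau)$ of the closed superlevel set $\{V \ge \tau\}$. After
rigid alignment to the gold mesh $G$, the package samples points $x_i$ on
$S(\tau)$ and computes signed distances

$$ d_i = \pm \,\mathrm{dist}(x_i, G), $$

positive when $x_i$ lies outside $G$ (the reconstruction is locally larger
than the gold standard) and negative inside. The summary statistics are the
arithmetic mean $\bar d(\tau)$, the population standard deviation, and a
histogram with bins anchored at zero.

Under a symmetric point-spread function, blurring the binary object moves
intensity values but leaves the half-level set approximately on the true
surface, so $\bar d(\tau)$ is a monotonically decreasing function of $\tau$
that crosses zero near the half level $\tau_{1/2} = (I_{fg}+I_{bg})/2$.
`optimize_threshold()` exploits this: a coarse grid over a user bracket
locates the sign change of $\bar d$, then bisection on the sign refines it
until $|\bar d| <$ tolerance (default 0.005 mm) or the bracket is narrower
than the intensity resolution. Bisection on the *sign of the mean* was chosen
over golden-section on $|\bar d|$ because $|\bar d|$ is V-shaped with a
possibly flat noise floor at the bottom, where a unimodal line search can
stall; the sign of a monotone function is robust.

Rigid alignment happens in two stages, as in standard practice:

1. **Landmark stage.** Paired points picked on the two models are aligned by
   the closed-form least-squares solution (Kabsch/Arun): centre both sets,
   decompose the cross-covariance by SVD, and correct a possible reflection
   so $\det R = +1$. The unit tests verify this against a direct
   quaternion-parametrised minimisation.
2. **Surface stage.** Trimmed iterative closest point: a fixed, seeded,
   area-weighted sample of the moving surface is matched to exact closest
   points on the fixed surface (point-to-triangle projection through a
   bounding-volume hierarchy), the worst 10% of correspondences is dropped,
   and the update is solved by the same SVD method. Point-to-point residuals
   were preferred over point-to-plane: they are simpler, robust to noisy
   phantom normals, and the reference workflow gives no detail that would
   justify the extra machinery.

During threshold search the registration is computed once (from the
bracket-midpoint surface) and reused for every candidate $\tau$. Re-running
ICP per candidate would couple registration noise into the objective;
per-candidate re-registration remains available via `re_register = TRUE`.

## The synthetic phantom

No patient data ships with the package; every quantitative claim is
exercised on a synthetic phantom with known ground truth:

* **Geometry** — a horseshoe arch: a tube of radius 8 mm swept along a
  240 degree arc of radius 20 mm, with six sinusoidal bumps of 1 mm
  amplitude as tooth analogues. The swept-tube construction is deliberately
  non-anatomical: with a 360 degree span and no bumps it degenerates to a
  torus whose area $4\pi^2 R r$ anchors the generator's oracle tests, and an
  icosphere fixture provides analytic area, volume and distance checks.
* **CT analogue** — the mesh is voxelised (a voxel is foreground when its
  *centre* is inside the mesh — unambiguous, and consistent with the
  marching-cubes interpolation convention downstream), blurred with a
  Gaussian point-spread of $\sigma = 0.6$ mm, and optionally degraded with
  additive Gaussian noise. Intensities default to foreground 1000 over
  background 0, giving a clean ideal half-level at 500. The tube radius
  (8 mm) keeps the surface's mean curvature low: Gaussian blur shifts the
  half-level set inward by roughly $\sigma^2(\kappa_1+\kappa_2)/2$, about
  0.02 mm here, which is why threshold recovery tests accept an optimum a
  few intensity units below 500 rather than exactly at it.
* **Optical analogue** — the ground-truth mesh is moved into a different,
  recorded pose and every vertex is displaced along its normal by iid
  $N(0, \sigma^2)$ noise, $\sigma = 0.01$ mm by default (the stated accuracy
  of the reference scanner class). Structured-light error is dominantly
  along the line of sight, hence normal rather than isotropic displacement.

What the phantom does *not* emulate: beam hardening, metal artefacts,
scatter, patient motion, anatomical shape complexity, or spatially
correlated scanner noise. Passing the phantom suite therefore demonstrates
the correctness of the geometry/statistics pipeline and the threshold
search under idealised smooth-blur conditions — it does not certify
accuracy figures on clinical scans, whose artefacts the operator still
handles manually.

## Numerical choices worth knowing

* **Threshold comparison is `>=`.** Fixed so that voxel counts and masks are
  exactly reproducible; for $\tau_1 < \tau_2$ the $\tau_2$ mask is a strict
  subset of the $\tau_1$ mask.
* **Marching cubes** uses the classic symmetry-completed case table with
  vertices welded on lattice edges, so neighbouring cells share vertices
  exactly and the surface is watertight away from the grid border.
  Ambiguous cases are resolved consistently by the table; on the smooth
  blurred volumes this package targets, the isosurface is far from the
  pathological checkerboard configurations. No smoothing or decimation is
  applied — the deviation analysis must measure segmentation error, not
  post-processing.
* **Signed distance** uses exact point-to-triangle projection with the sign
  from the angle-weighted pseudo-normal of the closest feature; unit tests
  pin it to a brute-force all-triangles oracle (1e-12 mm) with signs from a
  generalized winding number.
* **Surface sampling is area-weighted vertex sampling** by default.
  Sampling face interiors would interpolate per-vertex scanner noise with
  barycentric weights, shrinking its variance by about one half
  ($E\sum w_i^2 = 1/2$ on a triangle) and thus understating the very noise
  floor the workflow is supposed to measure; vertex sampling preserves
  per-vertex measurement statistics. Face-interior sampling remains
  available (`method = "face"`).
* **Voxel-centre counting resonates with symmetric grids.** A unit sphere
  voxelised at 0.2 mm with the lattice aligned to its centre mis-estimates
  volume by 5–7% (classic lattice-point fluctuations at radius/spacing
  = 5); at generic alignments the error drops below ~2.5% and decreases
  with spacing. Volume oracles in the tests therefore place the grid in
  general position, and users comparing voxel counts against analytic
  volumes should too.
* **ICP details.** The moving surface is sampled once (seeded) before
  iterating, which makes the trimmed-RMS trace provably non-increasing;
  correspondences are re-trimmed every iteration. The reported headline
  `rms` is the *untrimmed* RMS — the honest noise-floor estimate — while
  convergence is judged on the trimmed RMS. Point-to-point ICP converges
  geometrically (about 0.93 per iteration on the arch phantom), so
  10-degree initial errors need roughly 130 iterations; the default cap is
  100 iterations (ample for the landmark-initialised poses the workflow
  produces), and callers starting further away should raise
  `max_iterations` — the pose-recovery tests use 200.
* **Population (1/n) standard deviation.** With $10^4$–$10^6$ surface
  samples the difference from the $1/(n-1)$ convention is negligible; the
  choice is fixed and recorded here.
* **`rotation_angle()`** uses the atan2 of the antisymmetric part rather
  than `acos` of the trace, whose resolution floor (~1.5e-8 rad) would mask
  the actual accuracy of the closed-form landmark solution.
* **Degenerate inputs.** Non-watertight meshes are rejected by voxelisation
  (inside test undefined) and by signed distance when orientation is
  inconsistent; empty masks, empty ROIs, single-slice DICOM series,
  non-uniform slice gaps (>1%), oblique DICOM orientations and isovalues
  outside the intensity range all raise errors rather than guessing.

## Problem sizes in the shipped tests

The reference study conditions are the phantom above, voxelised at 0.3 mm
(about 2.8 million voxels), with 20 000-point deviation fields. The
byte-reproducibility checks run the full study twice at an 8 000-point
sample budget, and trace-reproducibility uses a coarser 0.6 mm phantom —
determinism is independent of problem size, so those checks use the
smallest instance that still runs every pipeline stage.

## Known limitations

* Only axis-aligned volumes are supported; oblique DICOM orientations are
  rejected outright — silent misinterpretation of geometry is worse than
  refusal.
* The ROI mechanism (seed points + along-edge geodesic radius, or explicit
  vertex sets) is deliberately simple; it selects mating-surface patches
  but offers no freeform lasso.
* The threshold search assumes a single global threshold; spatially varying
  or multi-label segmentation is out of scope.
* `simulate_optical_scan()` perturbs the mesh vertices it is given; the
  nominal `sample_count` of the scanner is recorded as metadata rather than
  driving a remeshing, so mesh resolution doubles as scan resolution.
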