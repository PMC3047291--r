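#' Synthetic dental-arch phantom specification
#'
#' Parameters of the paired synthetic data that stand in for the patient's
#' radiographic template / gypsum cast: a bright rigid horseshoe ("arch")
#' voxelised at CT-like spacing with partial-volume blur and noise, plus a
#' noisy surface sampling of the same object in a different, known pose (the
#' optical-scan analogue).
#'
#' Defaults define the package's reference study conditions: an arch of
#' 20 mm radius swept with an 8 mm tube over 240 degrees, six sinusoidal
#' 1 mm bumps as tooth analogues, CT-like contrast `fg = 1000` over
#' `bg = 0` (so the ideal half-level isovalue is 500), a 0.6 mm
#' partial-volume point-spread sigma, and an optical scanner noise of
#' 0.01 mm (the stated overall accuracy of structured-light scanners of
#' this class).
#'
#' @param arch_radius radius of the arch centreline (mm); must exceed
#'   `tube_radius`.
#' @param tube_radius radius of the swept tube (mm), > 0.
#' @param arc_span angular span of the arch in degrees, in (0, 360]; 360
#'   closes the sweep into a torus.
#' @param bump_count integer number of sinusoidal bumps along the arc.
#' @param bump_amplitude bump amplitude (mm), modulating the tube radius.
#' @param fg_intensity,bg_intensity foreground/background intensity (CT
#'   units); `fg_intensity > bg_intensity`.
#' @param psf_sigma Gaussian point-spread sigma of the simulated CT (mm).
#' @param ct_noise_sd additive CT noise SD (CT units).
#' @param optical_noise_sd per-vertex optical scanner noise SD (mm).
#' @param optical_sample_count nominal number of measured surface points of
#'   the optical scan (>= 3); recorded with the scan.
#' @param true_pose [rigid_transform()] carrying the phantom into the
#'   optical scanner's coordinate frame (the ground-truth pose that
#'   registration must recover).
#' @param seed integer seed for all stochastic stages.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(arch_radius = 20, tube_radius = 8, arc_span = 240,
                         bump_count = 6L, bump_amplitude = 1,
                         fg_intensity = 1000, bg_intensity = 0,
                         psf_sigma = 0.6, ct_noise_sd = 0,
                         optical_noise_sd = 0.01,
                         optical_sample_count = 20000L,
                         true_pose = rigid_transform(
                           rotation_about_axis(c(0.2, 0.3, 1), 5 * pi / 180),
                           c(2, -1, 1)),
                         seed = 1L) {
  spec <- list(arch_radius = arch_radius, tube_radius = tube_radius,
               arc_span = arc_span, bump_count = as.integer(bump_count),
               bump_amplitude = bump_amplitude, fg_intensity = fg_intensity,
               bg_intensity = bg_intensity, psf_sigma = psf_sigma,
               ct_noise_sd = ct_noise_sd, optical_noise_sd = optical_noise_sd,
               optical_sample_count = as.integer(optical_sample_count),
               true_pose = true_pose, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!(tube_radius > 0)) stop("invalid phantom spec: tube_radius must be > 0")
    if (!(arch_radius > tube_radius))
      stop("invalid phantom spec: arch_radius must exceed tube_radius")
    if (!(arc_span > 0 && arc_span <= 360))
      stop("invalid phantom spec: arc_span must be in (0, 360]")
    if (!(fg_intensity > bg_intensity))
      stop("invalid phantom spec: fg_intensity must exceed bg_intensity")
    if (psf_sigma < 0) stop("invalid phantom spec: psf_sigma must be >= 0")
    if (ct_noise_sd < 0 || optical_noise_sd < 0)
      stop("invalid phantom spec: noise SDs must be >= 0")
    if (optical_sample_count < 3)
      stop("invalid phantom spec: optical_sample_count must be >= 3")
    if (bump_count < 0) stop("invalid phantom spec: bump_count must be >= 0")
    if (bump_amplitude < 0)
      stop("invalid phantom spec: bump_amplitude must be >= 0")
    if (bump_amplitude >= tube_radius)
      stop("invalid phantom spec: bump_amplitude must be below tube_radius")
  })
  invisible(spec)
}

#' Horseshoe arch phantom mesh
#'
#' Closed, outward-oriented triangle mesh of a tube swept along a circular
#' arc, with the tube radius sinusoidally modulated along the arc
#' (tooth-analogue bumps). With `arc_span = 360` and `bump_amplitude = 0`
#' the result is a torus with analytic area `4 pi^2 R r`, which anchors the
#' generator's oracle tests. Geometry is fully determined by the
#' [phantom_spec()]: two calls with one spec give bitwise-identical meshes.
#'
#' @param spec a [phantom_spec()].
#' @param edge_target approximate triangle edge length (mm); controls mesh
#'   resolution.
#' @return A watertight [tri_mesh()] in mm.
#' @export
make_arch_mesh <- function(spec, edge_target = 0.5) {
  validate_phantom_spec(spec)
  R <- spec$arch_radius; r0 <- spec$tube_radius
  span <- spec$arc_span * pi / 180
  closed <- isTRUE(all.equal(spec$arc_span, 360))
  arc_len <- R * span
  nu <- max(16L, ceiling(arc_len / edge_target))
  nv <- max(24L, ceiling(2 * pi * r0 / edge_target))

  # arc parameter: nu+1 rings for an open arch, nu rings (periodic) for torus
  nring <- if (closed) nu else nu + 1L
  th <- -span / 2 + span * (seq_len(nring) - 1L) / nu
  ph <- 2 * pi * (seq_len(nv) - 1L) / nv

  # tube radius modulated along the arc
  u <- (th + span / 2) / span  # in [0, 1]
  rad <- r0 + spec$bump_amplitude * sin(2 * pi * spec$bump_count * u)

  # ring frame: radial direction in xy-plane, binormal = z
  verts <- matrix(0, nring * nv, 3)
  for (i in seq_len(nring)) {
    nx <- cos(th[i]); ny <- sin(th[i])
    cx <- R * nx; cy <- R * ny
    rows <- (i - 1L) * nv + seq_len(nv)
    verts[rows, 1] <- cx + rad[i] * cos(ph) * nx
    verts[rows, 2] <- cy + rad[i] * cos(ph) * ny
    verts[rows, 3] <- rad[i] * sin(ph)
  }

  vid <- function(i, j) {  # 1-based ring i, around-tube j (wraps)
    ii <- if (closed) ((i - 1L) %% nring) + 1L else i
    jj <- ((j - 1L) %% nv) + 1L
    (ii - 1L) * nv + jj
  }
  nquad_u <- if (closed) nring else nring - 1L
  faces <- vector("list", nquad_u)
  for (i in seq_len(nquad_u)) {
    j <- seq_len(nv)
    a <- vid(i, j); b <- vid(i + 1L, j)
    c <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
    faces[[i]] <- rbind(cbind(a, b, c), cbind(a, c, d))
  }
  F <- do.call(rbind, faces)
  V <- verts

  if (!closed) {
    # cap both ends with triangle fans around the ring centroid
    for (end in c(1L, nring)) {
      ring <- (end - 1L) * nv + seq_len(nv)
      centre <- colMeans(V[ring, , drop = FALSE])
      V <- rbind(V, centre)
      cid <- nrow(V)
      j <- seq_len(nv)
      a <- vid(end, j); b <- vid(end, j + 1L)
      fan <- if (end == 1L) cbind(cid, a, b) else cbind(cid, b, a)
      F <- rbind(F, fan)
    }
  }
  mesh <- tri_mesh(V, F)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times, vertices projected onto the
#' sphere of the given radius; watertight with outward normals.
#'
#' @param radius sphere radius (mm), > 0.
#' @param subdivisions non-negative integer; 0 gives the 20-face icosahedron.
#' @return A [tri_mesh()].
#' @export
make_sphere_mesh <- function(radius = 1, subdivisions = 3L) {
  if (!(radius > 0)) stop("invalid parameter: radius must be > 0")
  if (subdivisions < 0) stop("invalid parameter: subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edgekey <- new.env(hash = TRUE)
    nV <- nrow(V)
    Vlist <- list(V)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edgekey[[key]]
      if (!is.null(id)) return(id)
      nV <<- nV + 1L
      Vlist[[length(Vlist) + 1L]] <<- (V[a, ] + V[b, ]) / 2
      edgekey[[key]] <- nV
      nV
    }
    newF <- matrix(0L, nrow(F) * 4L, 3L)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF[4 * (f - 1) + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    V <- do.call(rbind, Vlist)
    F <- newF
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  tri_mesh(V, F)
}

#' Voxelise a watertight mesh into a binary-intensity volume
#'
#' Each voxel whose centre lies inside the mesh gets `fg`, every other voxel
#' `bg` (inside/outside decided at voxel centres by the signed distance to
#' the mesh). The grid covers the mesh bounding box plus `padding` on all
#' sides, with `origin` set so that voxel centres sit at
#' `origin + index * spacing`.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param spacing voxel spacing in mm (scalar or length-3).
#' @param padding padding added around the bounding box (mm).
#' @param fg,bg foreground/background intensities.
#' @return A [voxel_volume()].
#' @export
voxelize_mesh <- function(mesh, spacing, padding = 3, fg = 1000, bg = 0) {
  spacing <- if (length(spacing) == 1L) rep(spacing, 3) else as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (!is_watertight(mesh))
    stop("voxelize_mesh needs a watertight mesh: inside test undefined otherwise")
  lo <- apply(mesh$vertices, 2, min) - padding
  hi <- apply(mesh$vertices, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  origin <- lo
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  centres <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  bvh <- cpp_bvh_build(mesh$vertices, mesh$faces)
  d <- cpp_bvh_query(bvh, centres)$distance
  vol <- array(ifelse(d < 0, fg, bg), dim = dims)
  voxel_volume(vol, spacing, origin)
}

#' Simulate CT acquisition: partial-volume blur plus noise
#'
#' Applies a Gaussian blur with physical sigma `psf_sigma` (converted
#' per-axis through the voxel spacing; kernel truncated at 4 sigma,
#' replicate boundary) and then adds zero-mean Gaussian noise with SD
#' `noise_sd`. The blur emulates the smooth partial-volume intensity
#' transition across the object boundary that makes the segmentation
#' threshold matter in the first place. Spacing and origin are unchanged.
#'
#' @param volume a [voxel_volume()].
#' @param psf_sigma Gaussian sigma in mm, >= 0 (0 = no blur).
#' @param noise_sd noise SD in intensity units, >= 0.
#' @param seed integer seed for the noise.
#' @return A [voxel_volume()].
#' @export
simulate_ct <- function(volume, psf_sigma = 0.6, noise_sd = 0, seed = 1L) {
  if (psf_sigma < 0) stop("psf_sigma must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  data <- volume$data
  dims <- dim(data)
  if (psf_sigma > 0) {
    v <- as.numeric(data)
    for (axis in 0:2) {
      sig <- psf_sigma / volume$spacing[axis + 1]
      r <- max(1L, ceiling(4 * sig))
      k <- stats::dnorm(seq(-r, r), sd = sig)
      k <- k / sum(k)
      v <- cpp_conv_axis(v, dims, k, axis)
    }
    data <- array(v, dims)
  }
  if (noise_sd > 0) {
    data <- data + withr::with_seed(seed,
      array(stats::rnorm(length(data), sd = noise_sd), dims))
  }
  voxel_volume(data, volume$spacing, volume$origin)
}

#' Simulate an optical scan of a mesh
#'
#' Moves the mesh into the scanner frame by `pose` and perturbs every vertex
#' along its (pre-noise) outward normal by iid `N(0, noise_sd^2)` —
#' structured-light error is dominantly along the line of sight / surface
#' normal rather than isotropic. The applied pose, nominal sample count and
#' seed are recorded as attributes (`"pose"`, `"sample_count"`, `"seed"`) so
#' that registration tests can recover the ground truth.
#'
#' @param mesh a [tri_mesh()].
#' @param sample_count nominal number of measured points (>= 3); recorded.
#' @param noise_sd per-vertex noise SD in mm (the scanner's accuracy; 0.01
#'   for the reference device).
#' @param pose a [rigid_transform()] applied before the noise is observed.
#' @param seed integer seed.
#' @return A [tri_mesh()] in the scanner frame.
#' @export
simulate_optical_scan <- function(mesh, sample_count = 20000L,
                                  noise_sd = 0.01,
                                  pose = rigid_transform(), seed = 1L) {
  if (sample_count < 3) stop("sample_count must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  out <- apply_transform(mesh, pose)
  if (noise_sd > 0) {
    vn <- vertex_normals(out)
    d <- withr::with_seed(seed, stats::rnorm(nrow(out$vertices), sd = noise_sd))
    out$vertices <- out$vertices + vn * d
  }
  attr(out, "pose") <- pose
  attr(out, "sample_count") <- as.integer(sample_count)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Generate the full synthetic CT + optical pair of a phantom spec
#'
#' Convenience wrapper: builds the arch mesh, voxelises and CT-simulates it,
#' and produces the noisy optical scan in the phantom's true pose.
#'
#' @param spec a [phantom_spec()].
#' @param spacing CT voxel spacing in mm (scalar or length-3).
#' @param padding grid padding in mm.
#' @return list with elements `mesh` (ground-truth surface), `ct`
#'   (a [voxel_volume()]), `optical` (a [tri_mesh()] in the scanner frame).
#' @export
make_phantom_pair <- function(spec, spacing = 0.3, padding = 3) {
  mesh <- make_arch_mesh(spec)
  ideal <- voxelize_mesh(mesh, spacing = spacing, padding = padding,
                         fg = spec$fg_intensity, bg = spec$bg_intensity)
  ct <- simulate_ct(ideal, psf_sigma = spec$psf_sigma,
                    noise_sd = spec$ct_noise_sd, seed = spec$seed)
  optical <- simulate_optical_scan(mesh, sample_count = spec$optical_sample_count,
                                   noise_sd = spec$optical_noise_sd,
                                   pose = spec$true_pose, seed = spec$seed + 1L)
  list(mesh = mesh, ct = ct, optical = optical)
}
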