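test_that("full-span bump-free arch is a torus with the analytic area", {
  spec <- phantom_spec(arc_span = 360, bump_amplitude = 0)
  tor <- make_arch_mesh(spec)
  expect_true(is_watertight(tor))
  analytic <- 4 * pi^2 * spec$arch_radius * spec$tube_radius
  expect_lt(abs(mesh_area(tor) - analytic) / analytic, 0.02)
})

test_that("arch phantom is closed, outward-oriented and deterministic", {
  arch <- arch_mesh_default()
  audit <- edge_audit(arch)
  expect_identical(audit$n_boundary, 0L)      # every edge shared by 2 faces
  expect_identical(audit$n_nonmanifold, 0L)
  expect_identical(audit$n_inconsistent, 0L)
  expect_gt(mesh_volume(arch), 0)             # outward orientation

  again <- make_arch_mesh(phantom_spec())
  expect_identical(again$vertices, arch$vertices)
  expect_identical(again$faces, arch$faces)
})

test_that("phantom_spec rejects violated invariants by name", {
  expect_error(phantom_spec(tube_radius = -1), "tube_radius")
  expect_error(phantom_spec(arch_radius = 2, tube_radius = 5), "arch_radius")
  expect_error(phantom_spec(arc_span = 400), "arc_span")
  expect_error(phantom_spec(fg_intensity = 0, bg_intensity = 10), "fg_intensity")
  expect_error(phantom_spec(psf_sigma = -0.1), "psf_sigma")
  expect_error(phantom_spec(optical_sample_count = 2), "optical_sample_count")
})

test_that("icosphere: exact radii, analytic area, icosahedron base", {
  expect_identical(nrow(make_sphere_mesh(1, 0)$faces), 20L)
  s3 <- make_sphere_mesh(1, 3)
  expect_equal(sqrt(rowSums(s3$vertices^2)), rep(1, nrow(s3$vertices)),
               tolerance = 1e-12)
  s4 <- make_sphere_mesh(1, 4)
  expect_lt(abs(mesh_area(s4) - 4 * pi) / (4 * pi), 0.005)
  expect_true(is_watertight(s4))
  expect_gt(mesh_volume(s4), 0)
  expect_error(make_sphere_mesh(-2), "radius")
})

test_that("voxelisation recovers the sphere volume and refines with spacing", {
  sm <- make_sphere_mesh(1, 3)
  # grid in general position relative to the sphere (padding not a lattice
  # multiple of spacing): voxel-centre counting resonates at symmetric
  # alignments, which is a property of the quadrature, not of the mesh
  v <- voxelize_mesh(sm, spacing = 0.2, padding = 0.53, fg = 1, bg = 0)
  est <- sum(v$data) * 0.2^3
  expect_lt(abs(est - 4 * pi / 3) / (4 * pi / 3), 0.05)

  s4 <- make_sphere_mesh(1, 4)
  errs <- vapply(c(0.4, 0.2), function(sp) {
    vv <- voxelize_mesh(s4, spacing = sp, padding = 0.53, fg = 1, bg = 0)
    abs(sum(vv$data) * sp^3 - 4 * pi / 3)
  }, 0)
  expect_lt(errs[2], errs[1])
})

test_that("voxelisation grid covers bbox plus padding; degenerate intensities", {
  sm <- make_sphere_mesh(1, 2)
  v0 <- voxelize_mesh(sm, spacing = 0.25, padding = 0, fg = 7, bg = 7)
  # padding 0: the first voxel centre is the bounding-box corner
  expect_equal(v0$origin, apply(sm$vertices, 2, min))
  d <- dim(v0$data)
  top <- voxel_index_to_world(v0, d)
  expect_true(all(top >= apply(sm$vertices, 2, max) - 1e-12))
  expect_true(all(v0$data == 7))  # fg == bg -> constant volume

  open_mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(1:3))
  expect_error(voxelize_mesh(open_mesh, 0.5), "watertight")
})

test_that("simulate_ct: identity, constant fields, interface midlevel, linearity", {
  vol <- voxel_volume(array(runif(4 * 5 * 6), c(4, 5, 6)), c(1, 1, 1))
  out <- simulate_ct(vol, psf_sigma = 0, noise_sd = 0)
  expect_identical(out$data, vol$data)

  const <- voxel_volume(array(42, c(6, 6, 6)), 0.5)
  blur <- simulate_ct(const, psf_sigma = 1, noise_sd = 0)
  expect_equal(blur$data, const$data, tolerance = 1e-12)

  # half-space split: by kernel symmetry the two voxels flanking the
  # interface average to exactly (fg + bg) / 2
  half <- array(0, c(8, 8, 24))
  half[, , 13:24] <- 1000
  hv <- simulate_ct(voxel_volume(half, 0.3), psf_sigma = 0.6, noise_sd = 0)
  interface <- (hv$data[4, 4, 12] + hv$data[4, 4, 13]) / 2
  expect_equal(interface, 500, tolerance = 1e-9)

  # blur linearity in the input intensities
  a <- 3.7
  scaled <- simulate_ct(voxel_volume(vol$data * a, c(1, 1, 1)),
                        psf_sigma = 0.8, noise_sd = 0)
  base <- simulate_ct(vol, psf_sigma = 0.8, noise_sd = 0)
  expect_equal(scaled$data, base$data * a, tolerance = 1e-9)

  # seeded noise is reproducible
  n1 <- simulate_ct(vol, psf_sigma = 0, noise_sd = 5, seed = 9L)
  n2 <- simulate_ct(vol, psf_sigma = 0, noise_sd = 5, seed = 9L)
  expect_identical(n1$data, n2$data)
})

test_that("simulate_optical_scan: rigid motion exact, noise along normals", {
  mesh <- make_sphere_mesh(5, 2)
  idm <- simulate_optical_scan(mesh, noise_sd = 0)
  expect_identical(idm$vertices, mesh$vertices)

  tf <- rigid_transform(rotation_about_axis(c(1, 0, 1), 0.3), c(1, 2, -1))
  moved <- simulate_optical_scan(mesh, noise_sd = 0, pose = tf)
  expect_equal(moved$vertices, apply_transform(mesh$vertices, tf),
               tolerance = 1e-12)
  expect_identical(attr(moved, "pose"), tf)

  # vertex noise sigma = 0.01 along radial normals: mean |displacement| is
  # the half-normal mean sigma * sqrt(2/pi), checked with 10% slack on a
  # mesh fine enough that the sample mean has settled
  fine <- make_sphere_mesh(5, 4)
  noisy <- simulate_optical_scan(fine, noise_sd = 0.01, seed = 2L)
  d <- abs(sqrt(rowSums(noisy$vertices^2)) - 5)
  expect_lt(mean(d), 0.01 * sqrt(2 / pi) * 1.1)
  expect_gt(mean(d), 0.01 * sqrt(2 / pi) * 0.9)

  # identical seeds give bitwise-identical scans
  again <- simulate_optical_scan(fine, noise_sd = 0.01, seed = 2L)
  expect_identical(again$vertices, noisy$vertices)
})
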