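test_that("signed distance: analytic sphere values and surface zeros", {
  s4 <- make_sphere_mesh(1, 4)
  d <- signed_distances(rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, -2)), s4)
  expect_equal(d, c(1, 1, 1), tolerance = 0.01)     # faceting tolerance
  expect_equal(signed_distances(c(0, 0, 0), s4), -1, tolerance = 0.01)
  expect_equal(signed_distances(s4$vertices[1, ], s4), 0, tolerance = 1e-12)
})

test_that("signed distance equals the brute-force all-triangles oracle", {
  withr::with_seed(21, {
    # magnitude on unoriented 50-triangle soups
    for (rep in 1:3) {
      soup <- random_soup_mesh(50)
      q <- matrix(runif(3 * 40, -3, 3), ncol = 3)
      bvh_d <- abs(signed_distances(q, soup))
      oracle <- vapply(seq_len(nrow(q)), function(i)
        oracle_unsigned_distance(q[i, ], soup), 0)
      expect_lt(max(abs(bvh_d - oracle)), 1e-12)
    }
    # sign (winding-number oracle) on watertight star-shaped meshes
    star <- random_star_mesh(subdiv = 1)
    q <- matrix(runif(3 * 60, -1.5, 1.5), ncol = 3)
    got <- signed_distances(q, star)
    oracle <- vapply(seq_len(nrow(q)), function(i)
      oracle_signed_distance(q[i, ], star), 0)
    expect_lt(max(abs(got - oracle)), 1e-12)
  })
})

test_that("deviation magnitude is invariant under joint rigid motion", {
  withr::with_seed(22, {
    star <- random_star_mesh(subdiv = 1)
    q <- matrix(runif(30, -1.5, 1.5), ncol = 3)
    d0 <- signed_distances(q, star)
    g <- random_rigid_transform()
    d1 <- signed_distances(apply_transform(q, g), apply_transform(star, g))
    expect_lt(max(abs(abs(d1) - abs(d0))), 1e-9)
    expect_identical(sign(d1), sign(d0))
  })
})

test_that("inconsistently oriented gold meshes are rejected", {
  s <- make_sphere_mesh(1, 1)
  s$faces[1, ] <- s$faces[1, c(1, 3, 2)]  # flip one face
  expect_error(signed_distances(c(2, 0, 0), s), "oriented")
})

test_that("ROI selection: full set, geodesic patches, disjoint unions", {
  arch <- arch_mesh_default()
  all_roi <- roi_spec(vertex_indices = seq_len(nrow(arch$vertices)))
  sub <- select_roi(arch, all_roi)
  expect_identical(nrow(sub$faces), nrow(arch$faces))
  expect_equal(mesh_area(sub), mesh_area(arch))

  top <- arch$vertices[which.max(arch$vertices[, 3]), ]
  patch <- select_roi(arch, roi_spec(seed_points = top, radius = 5))
  expect_gt(mesh_area(patch), 0)
  expect_lt(mesh_area(patch), mesh_area(arch))

  # two far-apart seeds give the union of their separate patches
  bottom <- arch$vertices[which.min(arch$vertices[, 3]), ]
  p1 <- select_roi(arch, roi_spec(seed_points = top, radius = 3))
  p2 <- select_roi(arch, roi_spec(seed_points = bottom, radius = 3))
  both <- select_roi(arch, roi_spec(seed_points = rbind(top, bottom),
                                    radius = 3))
  expect_identical(nrow(both$faces), nrow(p1$faces) + nrow(p2$faces))

  expect_error(roi_spec(), "vertex_indices or seed_points")
  expect_error(select_roi(arch, roi_spec(vertex_indices = 1L)), "no complete face")
})

test_that("compare_surfaces recovers analytic normal offsets of a sphere", {
  gold <- make_sphere_mesh(10, 4)
  zero <- compare_surfaces(gold, gold, sample_count = 4000L, seed = 3L)
  expect_lt(max(abs(zero$distances)), 1e-9)

  vn <- vertex_normals(gold)
  bigger <- gold; bigger$vertices <- gold$vertices + 0.1 * vn
  st_plus <- deviation_stats(compare_surfaces(bigger, gold,
                                              sample_count = 8000L, seed = 3L))
  expect_equal(st_plus$mean, 0.1, tolerance = 0.005)

  smaller <- gold; smaller$vertices <- gold$vertices - 0.2 * vn
  st_minus <- deviation_stats(compare_surfaces(smaller, gold,
                                               sample_count = 8000L, seed = 3L))
  expect_equal(st_minus$mean, -0.2, tolerance = 0.005)

  # enlarging strictly raises the mean; shrinking strictly lowers it
  expect_gt(st_plus$mean, 0)
  expect_lt(st_minus$mean, 0)
})

test_that("deviation statistics: closed forms, histogram conservation, rendering", {
  z <- deviation_stats(rep(0, 10))
  expect_identical(c(z$mean, z$sd), c(0, 0))

  pm <- deviation_stats(c(-1, 1), bin_width = 0.5)
  expect_identical(pm$mean, 0)
  expect_identical(pm$sd, 1)            # population convention
  expect_identical(sum(pm$counts), 2L)
  expect_lte(pm$breaks[1], -1)
  expect_gte(pm$breaks[length(pm$breaks)], 1)

  withr::with_seed(30, {
    d <- rnorm(500, sd = 0.2)
    st <- deviation_stats(d)
    expect_identical(sum(st$counts), 500L)
    expect_equal(st$sd, sqrt(mean((d - mean(d))^2)))
    expect_true(any(st$breaks == 0))    # bins anchored at 0
  })

  st2 <- deviation_stats(c(-0.208, 0.192))  # mean -0.008, sd 0.200
  expect_identical(format_deviation_stats(st2),
                   "mean value -0.008 mm, SD 0.200 mm")
  expect_error(deviation_stats(numeric(0)), "empty")
})
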