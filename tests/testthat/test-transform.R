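test_that("rigid_transform validates rotations and composes as a group", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")

  a <- rigid_transform(rotation_about_axis(c(1, 1, 0), 0.4), c(1, 2, 3))
  expect_equal(compose_transform(rigid_transform(), a)$rotation, a$rotation)
  expect_equal(compose_transform(rigid_transform(), a)$translation, a$translation)

  inv <- invert_transform(a)
  id <- compose_transform(a, inv)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(id$translation)), 1e-12)
  back <- invert_transform(inv)
  expect_lt(max(abs(back$rotation - a$rotation)), 1e-12)

  # 90 degrees about z composed with itself = 180 degrees
  r90 <- rigid_transform(rotation_about_z(pi / 2))
  r180 <- compose_transform(r90, r90)
  expect_equal(r180$rotation, rotation_about_z(pi), tolerance = 1e-12)
})

test_that("apply_transform moves points, meshes and inverts exactly", {
  tf <- rigid_transform(rotation_about_axis(c(0, 1, 2), 1.1), c(0, 0, 5))
  pts <- matrix(rnorm(30), 10, 3)
  back <- apply_transform(apply_transform(pts, tf), invert_transform(tf))
  expect_lt(max(abs(back - pts)), 1e-12)

  shift <- rigid_transform(translation = c(0, 0, 5))
  moved <- apply_transform(pts, shift)
  expect_equal(colMeans(moved) - colMeans(pts), c(0, 0, 5))

  mesh <- make_sphere_mesh(1, 1)
  m2 <- apply_transform(mesh, rigid_transform())
  expect_identical(m2$vertices, mesh$vertices)
  expect_identical(m2$faces, mesh$faces)
})

test_that("landmark_register recovers known rigid motions exactly", {
  withr::with_seed(101, {
    for (n in c(3L, 6L, 10L)) {
      X <- matrix(rnorm(3 * n), n, 3)
      tf <- random_rigid_transform()
      Y <- apply_transform(X, tf)
      est <- landmark_register(landmark_set(X, Y))
      err <- compose_transform(est, invert_transform(tf))
      expect_lt(rotation_angle(err$rotation), 1e-9)
      expect_lt(sqrt(sum((apply_transform(X, est) - Y)^2)), 1e-9)
    }
  })
  # source == target -> identity
  X <- matrix(rnorm(15), 5, 3)
  est <- landmark_register(landmark_set(X, X))
  expect_lt(max(abs(est$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(est$translation)), 1e-9)
})

test_that("reflection guard: mirrored targets yield det(R) = +1 and residual > 0", {
  withr::with_seed(7, {
    X <- matrix(rnorm(12), 4, 3)
    Y <- X
    Y[, 1] <- -Y[, 1]
    est <- landmark_register(landmark_set(X, Y))
    expect_equal(det(est$rotation), 1, tolerance = 1e-9)
    expect_gt(kabsch_objective(est, X, Y), 1e-6)
  })
})

test_that("landmark_set rejects degenerate configurations", {
  expect_error(landmark_set(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))  # collinear
  expect_error(landmark_set(line, line + 1), "collinear")
})

test_that("SVD solution matches direct quaternion-search minimisation", {
  withr::with_seed(42, {
    for (n in c(3L, 5L, 8L)) {
      X <- matrix(rnorm(3 * n), n, 3)
      Y <- matrix(rnorm(3 * n), n, 3)  # no exact rigid fit exists
      est <- landmark_register(landmark_set(X, Y))
      expect_lte(kabsch_objective(est, X, Y), oracle_rigid_objective(X, Y) + 1e-6)
    }
  })
})

test_that("landmark files round-trip through the plain-text format", {
  withr::with_seed(3, {
    lm <- landmark_set(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3))
    path <- withr::local_tempfile(fileext = ".txt")
    write_landmarks(lm, path)
    back <- read_landmarks(path)
    expect_equal(back$source_points, lm$source_points, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(back$target_points, lm$target_points, tolerance = 1e-8,
                 ignore_attr = TRUE)
  })
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "0 0 0 1 0 0", "1 0 0 2 0 0", "", "0 1 0 1 1 0"), path2)
  expect_equal(nrow(read_landmarks(path2)$source_points), 3L)
})
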