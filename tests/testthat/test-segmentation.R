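test_that("threshold_mask implements the closed superlevel set", {
  const <- voxel_volume(array(100, c(2, 2, 2)), 1)
  expect_false(any(threshold_mask(const, 200)$data))
  expect_true(all(threshold_mask(const, min(const$data))$data))

  v <- voxel_volume(array((0:7) * 100, c(2, 2, 2)), 1)
  expect_identical(sum(threshold_mask(v, 350)$data), 4L)
  expect_identical(sum(threshold_mask(v, 400)$data), 4L)  # >= convention
  expect_identical(sum(threshold_mask(v, 401)$data), 3L)
})

test_that("masks nest: higher thresholds are subsets of lower ones", {
  withr::with_seed(12, {
    vol <- voxel_volume(array(runif(6^3, 0, 1000), c(6, 6, 6)), 1)
    taus <- sort(runif(4, 100, 900))
    for (i in seq_len(length(taus) - 1)) {
      lo <- threshold_mask(vol, taus[i])$data
      hi <- threshold_mask(vol, taus[i + 1])$data
      expect_true(all(lo[hi]))   # hi subset of lo
    }
  })
})

test_that("largest_component keeps the biggest blob with a stated tie-break", {
  a <- array(FALSE, c(10, 5, 5))
  a[2:4, 2:4, 2:4] <- TRUE  # 27 voxels
  m <- structure(list(data = a, spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                 class = "binary_mask")
  expect_identical(largest_component(m)$data, a)

  b <- a
  b[8:9, 2, 2] <- TRUE      # extra 2-voxel blob
  mb <- m; mb$data <- b
  expect_identical(largest_component(mb)$data, a)

  # two equal blobs: the one containing the smaller linear index wins
  c2 <- array(FALSE, c(10, 3, 3))
  c2[8:9, 2, 2] <- TRUE
  c2[2:3, 2, 2] <- TRUE
  mc <- m; mc$data <- c2
  kept <- largest_component(mc)$data
  expect_true(kept[2, 2, 2] && !kept[8, 2, 2])

  me <- m; me$data <- array(FALSE, dim(a))
  expect_error(largest_component(me), "nothing segmented")
})

test_that("isosurface of the blurred sphere sits at the analytic radius", {
  fix <- blurred_sphere()
  iso <- extract_isosurface(fix$ct, 500, keep_largest = TRUE)
  expect_true(is_watertight(iso))
  r <- sqrt(rowSums(iso$vertices^2))
  expect_lt(abs(mean(r) - 8), 0.2)  # half the 0.4 mm voxel spacing
})

test_that("a single foreground voxel yields a small closed surface around it", {
  a <- array(0, c(7, 7, 7))
  a[4, 4, 4] <- 1000
  vol <- voxel_volume(a, c(0.5, 0.5, 0.5), origin = c(0, 0, 0))
  iso <- extract_isosurface(vol, 500)
  expect_true(is_watertight(iso))
  expect_gt(mesh_area(iso), 0)
  expect_gt(mesh_volume(iso), 0)
  centre <- voxel_index_to_world(vol, c(4, 4, 4))
  expect_lt(signed_distances(centre, iso), 0)  # voxel centre enclosed
})

test_that("enclosed volume decreases as the threshold rises", {
  fix <- blurred_sphere()
  vols <- vapply(c(300, 500, 700), function(tau)
    mesh_volume(extract_isosurface(fix$ct, tau, keep_largest = TRUE)), 0)
  expect_true(all(diff(vols) < 0))
})

test_that("isosurface vertices hug the mask boundary (shared world convention)", {
  fix <- blurred_sphere()
  tau <- 500
  iso <- extract_isosurface(fix$ct, tau, keep_largest = TRUE)
  mask <- threshold_mask(fix$ct, tau)
  fg <- which(mask$data, arr.ind = TRUE)
  # boundary voxels: foreground with at least one 6-neighbour background
  d <- dim(mask$data)
  is_boundary <- vapply(seq_len(nrow(fg)), function(r) {
    i <- fg[r, 1]; j <- fg[r, 2]; k <- fg[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    any(!mask$data[nb[ok, , drop = FALSE]])
  }, TRUE)
  bnd <- voxel_index_to_world(mask, fg[is_boundary, , drop = FALSE])
  vsub <- iso$vertices[seq(1, nrow(iso$vertices), by = 29), , drop = FALSE]
  mind <- apply(vsub, 1, function(p) sqrt(min(colSums((t(bnd) - p)^2))))
  expect_lt(max(mind), max(fix$ct$spacing) + 1e-9)
})

test_that("isovalues outside the intensity range are rejected", {
  fix <- blurred_sphere()
  expect_error(extract_isosurface(fix$ct, 2000), "outside")
  expect_error(extract_isosurface(fix$ct, min(fix$ct$data)), "outside")
})
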