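test_that("compare_pair: self-comparison is exactly zero", {
  sphere <- make_sphere_mesh(10, 3)
  p <- withr::local_tempfile(fileext = ".stl")
  write_mesh(sphere, p)
  rep <- compare_pair(p, p, skip_icp = TRUE, sample_count = 2000L, seed = 1L)
  expect_lt(abs(rep$stats$mean_mm), 1e-9)
  expect_lt(rep$stats$sd_mm, 1e-9)
  expect_identical(rep$stats$n, 2000L)
})

test_that("compare_pair recovers an analytic normal offset", {
  gold <- make_sphere_mesh(10, 4)
  bigger <- gold
  bigger$vertices <- gold$vertices + 0.1 * vertex_normals(gold)
  pg <- withr::local_tempfile(fileext = ".ply")
  pt <- withr::local_tempfile(fileext = ".ply")
  write_mesh(gold, pg)
  write_mesh(bigger, pt)
  out_json <- withr::local_tempfile(fileext = ".json")
  rep <- compare_pair(pt, pg, skip_icp = TRUE, sample_count = 8000L,
                      seed = 2L, out_json = out_json)
  expect_equal(rep$stats$mean_mm, 0.1, tolerance = 0.005)
  parsed <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  expect_equal(parsed$stats$mean_mm, rep$stats$mean_mm, tolerance = 1e-12)
  expect_true(!is.null(parsed$timestamp))
})

test_that("compare_pair with landmarks reaches the optical noise floor", {
  arch <- arch_mesh_default()
  pose <- rigid_transform(rotation_about_axis(c(1, 0, 2), 3 * pi / 180),
                          c(1, -2, 0.5))
  noisy <- simulate_optical_scan(arch, noise_sd = 0.05, pose = pose, seed = 6L)
  pt <- withr::local_tempfile(fileext = ".stl")
  pg <- withr::local_tempfile(fileext = ".stl")
  write_mesh(noisy, pt)   # test: the noisy scan
  write_mesh(arch, pg)    # gold: the exact cast
  lmf <- withr::local_tempfile(fileext = ".txt")
  withr::with_seed(8, {
    vi <- sample.int(nrow(arch$vertices), 5)
    write_landmarks(landmark_set(
      apply_transform(arch$vertices[vi, ], pose) , arch$vertices[vi, ]), lmf)
  })
  rep <- compare_pair(pt, pg, landmarks_path = lmf,
                      icp = icp_params(seed = 4L),
                      sample_count = 10000L, seed = 5L)
  expect_gt(rep$stats$sd_mm, 0.8 * 0.05)
  expect_lt(rep$stats$sd_mm, 1.2 * 0.05)
  expect_true(rep$icp$converged)
})

test_that("phantom study bundle: output contract and noiseless recovery", {
  spec <- phantom_spec(seed = 5L, optical_noise_sd = 0)
  dir <- withr::local_tempdir()
  study <- run_phantom_study(spec, out_dir = dir, spacing = 0.45,
                             sample_count = 6000L,
                             icp = icp_params(sample_count = 6000L, seed = 6L),
                             write_timestamp = FALSE)
  for (p in unlist(study$paths)) expect_true(file.exists(p))
  res <- jsonlite::read_json(study$paths$result, simplifyVector = TRUE)
  expect_true(all(c("tau_star", "trace", "comparison_table") %in% names(res)))
  expect_identical(res$comparison_table$label, c("low", "optimal", "high"))
  expect_identical(nrow(study$table), 3L)
  # noiseless phantom: the optimum threshold nulls the mean deviation
  expect_lt(abs(study$table$mean_mm[2]), 0.01)
  expect_gt(study$table$mean_mm[1], 0)   # low tau -> larger model
  expect_lt(study$table$mean_mm[3], 0)   # high tau -> smaller model
})

test_that("study reports are byte-identical across reruns with one seed", {
  spec <- phantom_spec(seed = 11L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  args <- list(spec = spec, spacing = 0.6, sample_count = 4000L,
               icp = icp_params(sample_count = 4000L, seed = 12L),
               write_timestamp = FALSE)
  do.call(run_phantom_study, c(args, list(out_dir = d1)))
  do.call(run_phantom_study, c(args, list(out_dir = d2)))
  for (f in list.files(d1)) {
    b1 <- readBin(file.path(d1, f), "raw", n = file.info(file.path(d1, f))$size)
    b2 <- readBin(file.path(d2, f), "raw", n = file.info(file.path(d2, f))$size)
    expect_identical(b1, b2, label = paste("bytes of", f))
  }
})
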