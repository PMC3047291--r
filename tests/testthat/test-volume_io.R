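test_that("NRRD round-trip preserves data, spacing and origin exactly", {
  withr::with_seed(5, {
    vol <- voxel_volume(array(rnorm(3 * 4 * 5), c(3, 4, 5)),
                        spacing = c(0.4, 0.5, 0.6), origin = c(-1, 2, 0.25))
    path <- withr::local_tempfile(fileext = ".nrrd")
    write_volume(vol, path)
    back <- read_volume(path)
    expect_identical(back$data, vol$data)
    expect_identical(back$spacing, vol$spacing)
    expect_identical(back$origin, vol$origin)
  })
  v2 <- voxel_volume(array(1:8, c(2, 2, 2)), 1)
  p2 <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(v2, p2)
  expect_identical(dim(read_volume(p2)$data), c(2L, 2L, 2L))
})

test_that("volume IO rejects unknown formats and invalid headers", {
  expect_error(read_volume("x.mha"), "unknown volume format")
  expect_error(write_volume(voxel_volume(array(0, c(2, 2, 2)), 1), "x.tif"),
               "unknown volume format")
  # header without spacing information
  path <- withr::local_tempfile(fileext = ".nrrd")
  con <- file(path, "wb")
  writeChar("NRRD0004\ntype: double\ndimension: 3\nsizes: 2 2 2\nencoding: raw\n\n",
            con, eos = NULL)
  writeBin(as.numeric(1:8), con, size = 8, endian = "little")
  close(con)
  expect_error(read_volume(path), "spacing|space directions")
})

test_that("DICOM series: metadata round-trip and slice sorting", {
  withr::with_seed(8, {
    data <- array(sample.int(2000L, 4 * 3 * 4, replace = TRUE) - 1000L,
                  c(4, 3, 4))
    dir <- withr::local_tempdir()
    write_dicom_series_fixture(dir, data, spacing = c(0.4, 0.4, 0.5),
                               origin = c(-10, 5, 2))
    vol <- read_dicom_series(dir)
    expect_equal(vol$spacing, c(0.4, 0.4, 0.5))
    expect_equal(vol$origin, c(-10, 5, 2))
    expect_equal(vol$data, data + 0)
  })
})

test_that("DICOM slices sort by position regardless of file order", {
  withr::with_seed(9, {
    data <- array(sample.int(500L, 3 * 3 * 5, replace = TRUE), c(3, 3, 5))
    dir1 <- withr::local_tempdir()
    paths <- write_dicom_series_fixture(dir1, data)
    # shuffle by renaming so lexicographic file order is scrambled
    dir2 <- withr::local_tempdir()
    perm <- sample(length(paths))
    for (k in seq_along(paths))
      file.copy(paths[perm[k]], file.path(dir2, sprintf("s%03d.dcm", k)))
    v1 <- read_dicom_series(dir1)
    v2 <- read_dicom_series(dir2)
    expect_identical(v2$data, v1$data)
    expect_identical(v2$origin, v1$origin)
  })
})

test_that("DICOM rescale slope/intercept applied; missing tags warn", {
  data <- array(100L, c(3, 3, 2))
  dir <- withr::local_tempdir()
  write_dicom_series_fixture(dir, data, slope = 2, intercept = -1000)
  vol <- read_dicom_series(dir)
  expect_true(all(vol$data == 100 * 2 - 1000))

  dir2 <- withr::local_tempdir()
  write_dicom_series_fixture(dir2, data, with_rescale = FALSE)
  expect_warning(v2 <- read_dicom_series(dir2), "rescale")
  expect_true(all(v2$data == 100))
})

test_that("DICOM series rejects degenerate or inconsistent input", {
  data <- array(0L, c(3, 3, 2))
  one <- withr::local_tempdir()
  write_dicom_slice(file.path(one, "s1.dcm"), data[, , 1], position = c(0, 0, 0))
  expect_error(read_dicom_series(one), "at least 2")

  mixed <- withr::local_tempdir()
  write_dicom_slice(file.path(mixed, "a.dcm"), data[, , 1],
                    position = c(0, 0, 0), series_uid = "1.1")
  write_dicom_slice(file.path(mixed, "b.dcm"), data[, , 2],
                    position = c(0, 0, 1), series_uid = "1.2")
  expect_error(read_dicom_series(mixed), "mixed SeriesInstanceUID")

  gap <- withr::local_tempdir()
  for (k in 1:3)
    write_dicom_slice(file.path(gap, sprintf("s%d.dcm", k)), data[, , 1],
                      position = c(0, 0, c(0, 0.5, 1.2)[k]))
  expect_error(read_dicom_series(gap), "non-uniform slice gap")

  oblique <- withr::local_tempdir()
  for (k in 1:2)
    write_dicom_slice(file.path(oblique, sprintf("s%d.dcm", k)), data[, , 1],
                      position = c(0, 0, k * 0.5),
                      orientation = c(0.96, 0.28, 0, -0.28, 0.96, 0))
  expect_error(read_dicom_series(oblique), "oblique")
})
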