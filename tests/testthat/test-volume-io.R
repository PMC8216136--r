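rand_vol <- function(dim = c(6, 5, 4)) {
  density_volume(array(round(runif(prod(dim), 0, 1200), 4), dim),
                 voxel_size_mm = 0.0607, offset_slices = 3L)
}

test_that("MetaImage round trip is bit-exact and keeps geometry", {
  v <- rand_vol()
  f <- withr::local_tempfile(fileext = ".mha")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(r$data, v$data)
  expect_equal(r$voxel_size_mm, signif(v$voxel_size_mm, 6))
  expect_identical(r$offset_slices, v$offset_slices)
})

test_that("NIfTI round trip preserves data and voxel size", {
  v <- rand_vol()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_equal(r$data, v$data, tolerance = 0)
  expect_equal(r$voxel_size_mm, v$voxel_size_mm)
})

test_that("label volumes round trip exactly", {
  lab <- array(sample(0:2, 4 * 4 * 4, replace = TRUE), c(4, 4, 4))
  f <- withr::local_tempfile(fileext = ".mha")
  write_volume(density_volume(lab), f)
  expect_identical(read_volume(f)$data, lab + 0)
})

test_that("validity masks travel as a companion file, not a sentinel value", {
  v <- rand_vol()
  v$valid[2, , ] <- FALSE
  f <- withr::local_tempfile(fileext = ".mha")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(r$valid, v$valid)
  expect_identical(r$data, v$data)
})

test_that("anisotropic NIfTI volumes are rejected", {
  img <- RNifti::asNifti(array(1, c(4, 4, 4)))
  RNifti::pixdim(img) <- c(0.0607, 0.0607, 0.2)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "isotropic")
})

test_that("calibration is linear and invertible to machine precision", {
  cal <- calibration(slope = 2, intercept = -50)
  expect_equal(apply_calibration(100, cal), 150)
  x <- runif(100, -500, 3000)
  expect_equal(apply_calibration(apply_calibration(x, cal), cal, inverse = TRUE),
               x, tolerance = 1e-12)
  f <- withr::local_tempfile(fileext = ".mha")
  write_volume(density_volume(array(100, c(2, 2, 2))), f)
  expect_equal(unique(as.vector(read_volume(f, cal = cal)$data)), 150)
})

test_that("manifests load sorted, and broken manifests fail loudly", {
  dir <- withr::local_tempdir()
  mk <- function(ses, off, n) {
    for (i in seq_along(off))
      write_volume(density_volume(array(0, c(n[i], 4, 4))),
                   file.path(dir, sprintf("%s_%d.mha", ses, off[i])))
    lapply(seq_along(off), function(i)
      list(file = sprintf("%s_%d.mha", ses, off[i]),
           offset_slices = off[i], n_slices = n[i]))
  }
  m <- list(voxel_size_mm = 0.0607, sessions = list(
    list(session = "W3", time_index = 2, casted = TRUE, vgs = 2,
         stacks = mk("W3", c(10, 0), c(10, 10))),
    list(session = "W1", time_index = 1, casted = FALSE, vgs = 1,
         stacks = mk("W1", 0, 20))))
  yaml::write_yaml(m, file.path(dir, "manifest.yaml"))
  b <- load_manifest(file.path(dir, "manifest.yaml"))
  expect_identical(b$sessions$session, c("W1", "W3"))
  st3 <- b$stacks[b$stacks$session == "W3", ]
  expect_identical(st3$offset_slices, c(0L, 10L))   # returned sorted

  m$sessions[[1]]$stacks[[1]]$offset_slices <- 5    # overlaps the other stack
  yaml::write_yaml(m, file.path(dir, "manifest.yaml"))
  expect_error(load_manifest(file.path(dir, "manifest.yaml")), "overlap")

  m$sessions[[1]]$stacks[[1]]$offset_slices <- 10
  m$sessions[[2]]$stacks[[1]]$file <- "missing.mha"
  yaml::write_yaml(m, file.path(dir, "manifest.yaml"))
  expect_error(load_manifest(file.path(dir, "manifest.yaml")), "W1")
})
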