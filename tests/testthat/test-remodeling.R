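test_that("the constrained Gaussian filter leaves constant volumes unchanged", {
  v <- density_volume(array(500, c(8, 8, 8)))
  expect_equal(constrained_gaussian_filter(v)$data, v$data, tolerance = 1e-12)
})

test_that("a unit impulse stays within the kernel support and keeps its mass", {
  v <- density_volume(array(0, c(9, 9, 9)))
  v$data[5, 5, 5] <- 1
  f <- constrained_gaussian_filter(v)$data
  expect_equal(sum(f), 1, tolerance = 1e-12)   # interior: weights sum to one
  expect_true(all(f[abs(slice.index(f, 1) - 5) > 1 |
                    abs(slice.index(f, 2) - 5) > 1 |
                    abs(slice.index(f, 3) - 5) > 1] == 0))
})

test_that("default parameters give a 3x3x3 kernel matching the closed form", {
  fp <- filter_params()
  expect_identical(remodelr:::filter_radius(fp), 1L)
  kern <- remodelr:::gaussian_kernel_3d(0.8, 1L)   # direct evaluation
  v <- density_volume(array(0, c(7, 7, 7)))
  v$data[4, 4, 4] <- 1
  f <- constrained_gaussian_filter(v, fp)$data
  expect_equal(f[3:5, 3:5, 3:5], kern, tolerance = 1e-12)
})

test_that("invalid voxels contribute neither weight nor value", {
  v <- density_volume(array(1000, c(5, 5, 5)))
  v$valid[3, 3, 3] <- FALSE
  v$data[3, 3, 3] <- 1e6          # must not leak into neighbours
  f <- constrained_gaussian_filter(v)$data
  expect_equal(f[2, 3, 3], 1000, tolerance = 1e-9)
})

test_that("thresholding is inclusive and nested across the schedule", {
  v <- density_volume(array(c(100, 200, 199), c(3, 1, 1)))
  expect_identical(as.vector(threshold_volume(v, 200)), c(FALSE, TRUE, FALSE))
  ph <- tiny_phantom()
  m200 <- threshold_volume(ph$volume, 200)
  m320 <- threshold_volume(ph$volume, 320)
  expect_true(all(m200[m320]))
  # counts match a brute-force comparison
  for (T in threshold_schedule()$densities)
    expect_identical(sum(threshold_volume(ph$volume, T)),
                     sum(ph$volume$data >= T))
})

test_that("formation and resorption fractions match a hand-enumerated 5^3 fixture", {
  d <- c(5, 5, 5)
  earlier <- array(0, d); later <- array(0, d)
  bone <- cbind(1:5, 1, 1)                  # 10 earlier bone voxels
  earlier[rbind(bone, cbind(1:5, 2, 1))] <- 400
  later <- earlier
  later[cbind(1:4, 3, 1)] <- 400            # 4 formed
  later[cbind(1:2, 1, 1)] <- 0              # 2 resorbed
  mask <- region_mask(array(2L, d))
  res <- formation_resorption(density_volume(earlier), density_volume(later),
                              mask, schedule = threshold_schedule(320, 680),
                              interval = "W1")
  row <- res[res$bone_type == "trabecular", ]
  expect_identical(row$earlier_voxels, 10L)
  expect_identical(row$formed_voxels, 4L)
  expect_identical(row$resorbed_voxels, 2L)
  expect_equal(row$formation_fraction, 0.4)
  expect_equal(row$resorption_fraction, 0.2)
  # swapping the sessions swaps formation and resorption exactly
  swapped <- formation_resorption(density_volume(later), density_volume(earlier),
                                  mask, schedule = threshold_schedule(320, 680))
  srow <- swapped[swapped$bone_type == "trabecular", ]
  expect_identical(srow$formed_voxels, row$resorbed_voxels)
  expect_identical(srow$resorbed_voxels, row$formed_voxels)
})

test_that("identical sessions yield all-zero fractions and NA only on empty cells", {
  ph <- tiny_phantom()
  f <- constrained_gaussian_filter(ph$volume)
  res <- formation_resorption(f, f, ph$mask)
  expect_true(all(res$formed_voxels == 0L))
  expect_true(all(res$resorbed_voxels == 0L))
  nonempty <- res$earlier_voxels > 0
  expect_true(all(res$formation_fraction[nonempty] == 0))
  expect_true(all(is.na(res$formation_fraction[!nonempty])))
})

test_that("central-slice profiles use floor(n/2), match geometry and are nonincreasing", {
  d <- c(10, 6, 6)
  v <- density_volume(array(0, d))
  v$data[6, , ] <- 500                      # 0-based slice floor(10/2) = 5
  mask <- region_mask(array(2L, d))
  pr <- central_slice_volumes(v, mask, threshold_schedule())
  tb <- pr[pr$bone_type == "trabecular", ]
  expect_identical(tb$voxels[tb$threshold == 200], 36L)
  expect_equal(tb$volume_mm3[tb$threshold == 200], 36 * v$voxel_size_mm^3)
  expect_identical(tb$voxels[tb$threshold == 680], 0L)
  ph <- tiny_phantom()
  pr2 <- central_slice_volumes(ph$volume, ph$mask)
  for (bt in unique(pr2$bone_type)) {
    cnt <- pr2$voxels[pr2$bone_type == bt]
    expect_true(all(diff(cnt) <= 0))
  }
})

test_that("BST-SNR follows its defining arithmetic and is scale invariant", {
  d <- c(6, 20, 20)
  v <- density_volume(array(0, d))
  cort <- array(FALSE, d); cort[, 9:12, 9:12] <- TRUE
  peri <- array(FALSE, d); peri[, 7:14, 7:14] <- TRUE
  v$data[cort] <- 800
  ring <- array(remodelr:::cpp_morph_box(peri, d, 5L, TRUE), d) & !peri
  v$data[ring] <- rep(c(50, -50), length.out = sum(ring))
  q <- bst_snr(v, cort, peri)
  expect_equal(q$cortical_mean, 800)
  expect_equal(q$surround_sd, sd(v$data[ring]))
  expect_equal(q$bst_snr, 800 / sd(v$data[ring]))
  v2 <- v; v2$data <- v$data * 2
  expect_equal(bst_snr(v2, cort, peri)$bst_snr, q$bst_snr, tolerance = 1e-12)
})

test_that("thresholded-difference comparator matches hand enumeration with cluster removal", {
  d <- c(7, 7, 7)
  earlier <- array(0, d)
  later <- earlier
  later[1:3, 1:2, 1] <- 200                 # 6-voxel formation cluster
  later[6:7, 7, c(1, 3)] <- 200             # two separated small clusters
  mask <- region_mask(array(2L, d))
  res <- thresholded_difference_remodeling(
    density_volume(earlier), density_volume(later), mask,
    diff_threshold = 125, min_cluster = 5)
  row <- res[res$bone_type == "trabecular", ]
  expect_identical(row$formed_voxels, 6L)           # only the 6-voxel cluster
  expect_identical(row$earlier_voxels, as.integer(prod(d)))  # common volume
  # with the cluster filter disabled every |delta| >= 125 voxel counts
  res1 <- thresholded_difference_remodeling(
    density_volume(earlier), density_volume(later), mask,
    diff_threshold = 125, min_cluster = 1)
  expect_identical(res1$formed_voxels[res1$bone_type == "trabecular"], 10L)
  # identical images: all zero
  res0 <- thresholded_difference_remodeling(
    density_volume(earlier), density_volume(earlier), mask)
  expect_true(all(res0$formed_voxels == 0L))
})

test_that("6- and 26-connectivity count diagonal clusters differently", {
  d <- c(5, 5, 5)
  earlier <- array(0, d); later <- earlier
  for (i in 1:5) later[i, i, 1] <- 200      # diagonal chain of 5
  mask <- region_mask(array(2L, d))
  r26 <- thresholded_difference_remodeling(density_volume(earlier),
                                           density_volume(later), mask,
                                           min_cluster = 5, connectivity = 26)
  r6 <- thresholded_difference_remodeling(density_volume(earlier),
                                          density_volume(later), mask,
                                          min_cluster = 5, connectivity = 6)
  expect_identical(r26$formed_voxels[r26$bone_type == "trabecular"], 5L)
  expect_identical(r6$formed_voxels[r6$bone_type == "trabecular"], 0L)
})
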