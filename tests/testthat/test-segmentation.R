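test_that("segmentation reproduces the generator's labels exactly on the noise-free phantom", {
  ph <- tiny_phantom()
  peri <- periosteal_contour(ph$volume)
  expect_identical(sum(peri != (ph$mask$labels > 0L)), 0L)
  sm <- split_cortical_trabecular(ph$volume, peri)
  expect_identical(sum(sm$labels != ph$mask$labels), 0L)
})

test_that("the periosteal mask contains all phantom bone above the seed threshold", {
  ph <- tiny_phantom()
  peri <- periosteal_contour(ph$volume)
  bone <- ph$volume$data >= 320 & ph$mask$labels > 0L
  expect_true(all(peri[bone]))
})

test_that("background noise changes the periosteal volume by under 2 percent", {
  ph <- tiny_phantom()
  clean <- sum(periosteal_contour(ph$volume))
  noisy <- apply_acquisition(ph$volume, acquisition_spec(noise_sd = 50, seed = 2))[[1]]
  expect_lt(abs(sum(periosteal_contour(noisy)) - clean) / clean, 0.02)
})

test_that("cortical and trabecular labels partition the periosteal region", {
  ph <- tiny_phantom()
  peri <- periosteal_contour(ph$volume)
  sm <- split_cortical_trabecular(ph$volume, peri)
  expect_identical(sum(sm$labels == 1L) + sum(sm$labels == 2L), sum(peri))
  expect_identical(sum(sm$labels == 1L & sm$labels == 2L), 0L)
})

test_that("a dense trabecular island not connected to the shell stays trabecular", {
  ph <- plain_phantom()
  v <- ph$volume
  ctr <- round(dim(v$data) / 2)
  v$data[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)] <- 800
  sm <- split_cortical_trabecular(v, periosteal_contour(v))
  expect_true(all(sm$labels[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)] == 2L))
})

test_that("the additive cortical rule is idempotent, commutative and a union", {
  ph <- tiny_phantom()
  peri <- periosteal_contour(ph$volume)
  a <- split_cortical_trabecular(ph$volume, peri)
  expect_identical(additive_cortical_mask(a, a)$labels, a$labels)
  # construct b: five extra cortical voxels disjoint from five in a modified a
  b <- a
  tb_idx <- which(a$labels == 2L)
  a$labels[tb_idx[1:5]] <- 1L
  b$labels[tb_idx[6:10]] <- 1L
  ab <- additive_cortical_mask(a, b)
  ba <- additive_cortical_mask(b, a)
  expect_identical(ab$labels, ba$labels)
  expect_identical(sum(ab$labels == 1L), sum(b$labels == 1L) + 5L)
  # a voxel cortical in one session and trabecular in the other is cortical
  expect_identical(unique(ab$labels[tb_idx[1:10]]), 1L)
})

test_that("pairwise masks partition: cortical + trabecular = periosteal union", {
  ph <- tiny_phantom()
  r <- apply_remodeling(ph$volume, ph$mask, remodeling_spec())
  ma <- split_cortical_trabecular(ph$volume, periosteal_contour(ph$volume))
  mb <- split_cortical_trabecular(r$volume, periosteal_contour(r$volume))
  pair <- additive_cortical_mask(ma, mb)
  peri_union <- ma$labels > 0L | mb$labels > 0L
  expect_identical((pair$labels > 0L), peri_union)
  expect_identical(sum(pair$labels == 1L) + sum(pair$labels == 2L),
                   sum(peri_union))
})

test_that("fracture partitions follow the slice interval and pass-through rules", {
  d <- c(500L, 4L, 4L)
  fx <- fracture_partition(d, c(100L, 160L))
  expect_identical(sum(apply(fx, 1, any)), 60L)
  expect_true(all(fx[101:160, , ]))
  vol <- array(runif(prod(d)) > 0.5, d)
  expect_identical(fracture_partition(d, vol), vol)
  expect_false(any(fracture_partition(d, NULL)))
  expect_error(fracture_partition(d, c(450L, 600L)), "outside")
})

test_that("region selection is a disjoint partition matching a brute-force count", {
  ph <- tiny_phantom()
  mask <- ph$mask
  mask$fracture <- fracture_partition(dim(mask$labels), c(10L, 30L))
  cf <- region_select(mask, "cortical", "fracture")
  tf <- region_select(mask, "trabecular", "fracture")
  expect_false(any(cf & tf))
  un <- region_select(mask, "cortical", "fracture") |
    region_select(mask, "cortical", "intact") |
    region_select(mask, "trabecular", "fracture") |
    region_select(mask, "trabecular", "intact")
  expect_identical(un, mask$labels > 0L)
  # brute-force voxel loop on a sub-block
  sub <- expand.grid(i = 8:12, j = 30:34, k = 30:34)
  manual <- sum(mapply(function(i, j, k)
    mask$labels[i, j, k] == 1L && mask$fracture[i, j, k],
    sub$i, sub$j, sub$k))
  expect_identical(sum(cf[8:12, 30:34, 30:34]), as.integer(manual))
})
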