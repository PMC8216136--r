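test_that("zero-fraction remodeling returns the identical volume and empty ground truth", {
  ph <- tiny_phantom()
  sp <- remodeling_spec(tibble::tibble(region = "trabecular", threshold = 320,
                                       formation = 0, resorption = 0))
  r <- apply_remodeling(ph$volume, ph$mask, sp)
  expect_identical(r$volume$data, ph$volume$data)
  expect_true(all(r$truth$formed_voxels == 0L))
  expect_true(all(r$truth$resorbed_voxels == 0L))
})

test_that("unfiltered planting realises exactly round(fraction * earlier count)", {
  ph <- plain_phantom()
  sp <- remodeling_spec(tibble::tibble(region = "trabecular", threshold = 320,
                                       formation = 0.30, resorption = 0,
                                       formation_density = 380))
  r <- apply_remodeling(ph$volume, ph$mask, sp, filter = NULL)
  N <- sum(ph$volume$data >= 320 & ph$mask$labels == 2L)
  formed <- sum(r$volume$data >= 320 & ph$volume$data < 320 &
                  ph$mask$labels == 2L)
  expect_identical(formed, as.integer(round(0.30 * N)))
})

test_that("unfiltered resorption removes exactly round(fraction * earlier count) bone voxels", {
  ph <- plain_phantom()
  sp <- remodeling_spec(tibble::tibble(region = "cortical", threshold = 680,
                                       formation = 0, resorption = 0.10))
  r <- apply_remodeling(ph$volume, ph$mask, sp, filter = NULL)
  cell <- ph$mask$labels == 1L
  earlier <- sum(ph$volume$data >= 680 & cell)
  later <- sum(r$volume$data >= 680 & cell)
  expect_identical(later, earlier - as.integer(round(0.10 * earlier)))
})

test_that("filtered planting meets the requested fractions at the target cells", {
  ph <- tiny_phantom()
  r <- apply_remodeling(ph$volume, ph$mask, remodeling_spec())
  f0 <- constrained_gaussian_filter(ph$volume)$data
  tr320 <- r$truth[r$truth$bone_type == "trabecular" & r$truth$threshold == 320, ]
  N_tb <- sum(f0 >= 320 & ph$mask$labels == 2L)
  expect_identical(tr320$formed_voxels, as.integer(round(0.294 * N_tb)))
  expect_identical(tr320$resorbed_voxels, as.integer(round(0.286 * N_tb)))
  ct680 <- r$truth[r$truth$bone_type == "cortical" & r$truth$threshold == 680, ]
  N_ct <- sum(f0 >= 680 & ph$mask$labels == 1L)
  expect_identical(ct680$formed_voxels, as.integer(round(0.086 * N_ct)))
  expect_identical(ct680$resorbed_voxels, as.integer(round(0.087 * N_ct)))
})

test_that("planted formed and resorbed voxel sets are disjoint per cell", {
  ph <- tiny_phantom()
  r <- apply_remodeling(ph$volume, ph$mask, remodeling_spec())
  for (i in seq_len(nrow(r$truth))) {
    expect_length(intersect(r$truth$formed_idx[[i]], r$truth$resorbed_idx[[i]]), 0)
  }
})

test_that("infeasible remodeling requests fail with an informative error", {
  ph <- plain_phantom()
  sp <- remodeling_spec(tibble::tibble(region = "cortical", threshold = 680,
                                       formation = 0.95, resorption = 0,
                                       formation_density = 1200))
  expect_error(apply_remodeling(ph$volume, ph$mask, sp), "infeasible formation")
})

test_that("acquisition with identity transform and zero noise is the identity", {
  ph <- tiny_phantom()
  st <- apply_acquisition(ph$volume, acquisition_spec(noise_sd = 0))
  expect_identical(st[[1]]$data, ph$volume$data)
})

test_that("acquisition noise has the requested SD and casted inflation", {
  ph <- tiny_phantom()
  bg <- ph$volume$data == 0    # large background region
  st <- apply_acquisition(ph$volume, acquisition_spec(noise_sd = 50, seed = 3))
  expect_gt(sum(bg), 1e4)
  expect_lt(abs(sd(st[[1]]$data[bg]) - 50), 3)
  stc <- apply_acquisition(ph$volume, acquisition_spec(noise_sd = 50, seed = 3,
                                                       casted = TRUE))
  ratio <- sd(stc[[1]]$data[bg]) / sd(st[[1]]$data[bg])
  expect_lt(abs(ratio - 1.5), 0.05)
  # same seed twice: bit-identical
  st2 <- apply_acquisition(ph$volume, acquisition_spec(noise_sd = 50, seed = 3))
  expect_identical(st[[1]]$data, st2[[1]]$data)
})

test_that("stack layouts must tile without overlap and stay in range", {
  expect_error(acquisition_spec(stack_lengths_slices = c(20, 20),
                                stack_offsets_slices = c(0, 10)),
               "overlap")
  ph <- tiny_phantom()
  expect_error(apply_acquisition(ph$volume,
                                 acquisition_spec(stack_lengths_slices = 100,
                                                  stack_offsets_slices = 0)),
               "axial extent")
})

test_that("a transform that moves the bone off the grid is an acquisition error", {
  ph <- tiny_phantom()
  tr <- rigid_transform(translation_mm = c(0, 50, 0))
  expect_error(apply_acquisition(ph$volume,
                                 acquisition_spec(true_transform = tr,
                                                  noise_sd = 0)),
               "outside the grid")
})

test_that("a two-session study with no remodeling, motion or noise repeats the volume", {
  st <- make_longitudinal_study(
    config = tiny_config(),
    specs = remodeling_spec(tibble::tibble(region = "trabecular",
                                           threshold = 320, formation = 0,
                                           resorption = 0)),
    acquisitions = rep(list(acquisition_spec(noise_sd = 0)), 2),
    n_sessions = 2, seed = 5)
  expect_identical(st$sessions[[1]][[1]]$data, st$sessions[[2]][[1]]$data)
})

test_that("the six-session default design has exactly two casted sessions and full ground truth", {
  st <- fixture("study6", function()
    make_longitudinal_study(config = tiny_config(), n_sessions = 6, seed = 9))
  expect_identical(sum(st$manifest$sessions$casted), 2L)
  expect_identical(st$manifest$sessions$casted[1:2], c(TRUE, TRUE))
  # one ground-truth row per (interval, bone type, applicable threshold)
  expect_identical(nrow(st$ground_truth), 5L * (7L + 5L))
  expect_setequal(unique(st$ground_truth$interval), c("W1", "W3", "W5", "M3", "M6"))
})
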