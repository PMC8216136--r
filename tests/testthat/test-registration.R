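test_that("self-registration returns the identity within 0.05 voxel and 0.05 degree", {
  ph <- tiny_phantom()
  fit <- register_rigid_pyramid(ph$volume, ph$volume)
  expect_lt(max(abs(fit$transform$rotation_deg)), 0.05)
  expect_lt(max(abs(fit$transform$translation_mm)) / ph$volume$voxel_size_mm,
            0.05)
  expect_true(fit$report$converged)
})

test_that("a planted rigid motion is recovered within 0.2 voxel without noise", {
  cfg <- tiny_config()
  ph <- tiny_phantom()
  vox <- cfg$voxel_size_mm
  tr <- rigid_transform(c(3, 0, 0), c(0.5, 2.5, -1) * vox,
                        center_mm = phantom_center_mm(cfg))
  mov <- resample(ph$volume, invert_transform(tr), target = ph$volume)
  fit <- register_rigid_pyramid(mov, ph$volume)
  expect_lt(max_transform_err_voxels(fit$transform, tr, vox), 0.2)
  expect_lt(max(abs(fit$transform$rotation_deg - tr$rotation_deg)), 0.2)
})

test_that("planted motion is recovered within 0.5 voxel at calibrated noise", {
  cfg <- tiny_config()
  ph <- tiny_phantom()
  vox <- cfg$voxel_size_mm
  errs <- vapply(1:3, function(s) {
    set.seed(600 + s)
    tr <- rigid_transform(runif(3, -3, 3), runif(3, -3, 3) * vox,
                          center_mm = phantom_center_mm(cfg))
    mov <- apply_acquisition(ph$volume,
                             acquisition_spec(true_transform = tr,
                                              noise_sd = 220,
                                              seed = 700 + s))[[1]]
    fit <- register_rigid_pyramid(mov, ph$volume)
    max_transform_err_voxels(fit$transform, invert_transform(tr), vox)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
})

test_that("resampling through the identity is exact and integer shifts collapse", {
  ph <- tiny_phantom()
  out <- resample(ph$volume, rigid_transform(), target = ph$volume)
  expect_identical(out$data, ph$volume$data)
  vox <- ph$volume$voxel_size_mm
  sh <- resample(ph$volume, rigid_transform(translation_mm = c(2, 0, 0) * vox),
                 target = ph$volume)
  expect_equal(sh$data[3:48, , ], ph$volume$data[1:46, , ], tolerance = 1e-12)
  expect_false(any(sh$valid[1:2, , ]))
})

test_that("mean density is preserved within 1 percent under a sub-voxel shift", {
  ph <- tiny_phantom()
  sm <- constrained_gaussian_filter(ph$volume)   # smooth field
  vox <- sm$voxel_size_mm
  sh <- resample(sm, rigid_transform(translation_mm = c(0.4, 0.3, -0.2) * vox),
                 target = sm)
  common <- sh$valid
  expect_lt(abs(mean(sh$data[common]) - mean(sm$data[common])) /
              mean(sm$data[common]), 0.01)
})

test_that("registering A to B then B to A composes to the identity within 0.3 voxel", {
  cfg <- tiny_config()
  ph <- tiny_phantom()
  vox <- cfg$voxel_size_mm
  tr <- rigid_transform(c(2, -1, 1), c(1.5, -2, 1) * vox,
                        center_mm = phantom_center_mm(cfg))
  mov <- resample(ph$volume, invert_transform(tr), target = ph$volume)
  ab <- register_rigid_pyramid(mov, ph$volume)$transform
  ba <- register_rigid_pyramid(ph$volume, mov)$transform
  comp <- compose_transforms(ba, ab)
  expect_lt(max_transform_err_voxels(comp, rigid_transform(), vox), 0.3)
})

test_that("ladder registration recovers a single whole-arm transform on every stack", {
  cfg <- tiny_config()
  ph <- tiny_phantom()
  vox <- cfg$voxel_size_mm
  mk <- function(vol, tr, seed)
    apply_acquisition(vol, acquisition_spec(true_transform = tr, noise_sd = 0,
                                            stack_lengths_slices = rep(16, 3),
                                            stack_offsets_slices = c(0, 16, 32),
                                            seed = seed))
  sa <- mk(ph$volume, rigid_transform(), 1)
  tr <- rigid_transform(c(1.5, -1, 0.5), c(1, -1.5, 0.8) * vox,
                        center_mm = phantom_center_mm(cfg))
  sb <- mk(ph$volume, tr, 2)
  lad <- ladder_register_stacks(sa, sb)
  expect_true(all(lad$registered))
  for (i in seq_along(lad$transforms))
    expect_lt(max_transform_err_voxels(lad$transforms[[i]],
                                       invert_transform(tr), vox,
                                       pts = stack_points(sb[[i]])), 0.3)
  # zero motion: all three identity
  sb0 <- mk(ph$volume, rigid_transform(), 3)
  lad0 <- ladder_register_stacks(sa, sb0)
  for (i in seq_along(lad0$transforms))
    expect_lt(max_transform_err_voxels(lad0$transforms[[i]],
                                       rigid_transform(), vox,
                                       pts = stack_points(sb0[[i]])), 0.1)
})

test_that("a missing stack leaves a flagged gap and the rest registers", {
  ph <- tiny_phantom()
  mk <- function(seed)
    apply_acquisition(ph$volume,
                      acquisition_spec(noise_sd = 0,
                                       stack_lengths_slices = rep(16, 3),
                                       stack_offsets_slices = c(0, 16, 32),
                                       seed = seed))
  sa <- mk(1)
  sb <- mk(2)[1:2]
  lad <- ladder_register_stacks(sa, sb)
  expect_true(all(lad$registered))
  expect_false(any(lad$moving$valid[33:48, , ]))
})

test_that("the common evaluation region equals the brute-force set intersection", {
  d <- c(10, 10, 10)
  set.seed(4)
  va <- array(runif(prod(d)) > 0.2, d)
  vb <- array(runif(prod(d)) > 0.2, d)
  pa <- array(runif(prod(d)) > 0.5, d)
  pb <- array(runif(prod(d)) > 0.5, d)
  cr <- common_region(va, vb, pa, pb)
  manual <- va & vb & (pa | pb)
  expect_identical(cr, manual)
  expect_error(common_region(va, vb, array(FALSE, d), array(FALSE, d)),
               "empty")
})

test_that("registration strictly reduces apparent remodeling on a moved pair", {
  cfg <- tiny_config()
  ph <- tiny_phantom()
  vox <- cfg$voxel_size_mm
  tr <- rigid_transform(c(1, 0, 0), c(1, 2, -1) * vox,
                        center_mm = phantom_center_mm(cfg))
  mov <- resample(ph$volume, invert_transform(tr), target = ph$volume)
  fit <- register_rigid_pyramid(mov, ph$volume)
  reg <- resample(mov, fit$transform, target = ph$volume)
  un <- run_interval(ph$volume, mov)$remodeling
  re <- run_interval(ph$volume, reg)$remodeling
  cmp <- merge(as.data.frame(un), as.data.frame(re),
               by = c("bone_type", "threshold"), suffixes = c(".un", ".re"))
  ok <- cmp$earlier_voxels.un > 100
  total_un <- cmp$formation_fraction.un + cmp$resorption_fraction.un
  total_re <- cmp$formation_fraction.re + cmp$resorption_fraction.re
  expect_true(all(total_re[ok] < total_un[ok]))
})
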