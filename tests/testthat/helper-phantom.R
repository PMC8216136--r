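# shared fixtures, built once per test run

tiny_config <- function(...) {
  phantom_config(grid_shape = c(48, 72, 72),
                 cortex_outer_radius_mm = 1.7,
                 cortex_thickness_mm = 0.55,
                 ...)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

tiny_phantom <- function() fixture("tiny", function() generate_phantom(tiny_config()))

# a clean three-density phantom (no pores, no texture): exactly the
# geometric construction
plain_config <- function(...) {
  phantom_config(grid_shape = c(48, 72, 72),
                 cortex_outer_radius_mm = 1.7,
                 cortex_thickness_mm = 0.55,
                 cortical_porosity = 0, cortex_texture_sd = 0, ...)
}

plain_phantom <- function() fixture("plain", function() generate_phantom(plain_config()))

phantom_center_mm <- function(cfg) {
  (cfg$grid_shape - 1) / 2 * cfg$voxel_size_mm
}

max_transform_err_voxels <- function(t_est, t_true, voxel_mm, pts = NULL) {
  if (is.null(pts))
    pts <- matrix(c(1, 1, 1, 4, 1, 2, 2, 4, 1, 1, 2, 4, 3, 3, 3), 5, 3)
  max(abs(transform_points(t_est, pts) - transform_points(t_true, pts))) /
    voxel_mm
}

# points spanning one stack's own physical extent (where its transform acts)
stack_points <- function(stack) {
  d <- dim(stack$data); vox <- stack$voxel_size_mm
  lo <- stack$offset_slices * vox
  as.matrix(expand.grid(c(lo, lo + (d[1] - 1) * vox),
                        c(1, (d[2] - 2) * vox), c(1, (d[3] - 2) * vox)))
}
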