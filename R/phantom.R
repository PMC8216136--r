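# Digital radius phantom: a concentric-cylinder cortical shell around an
# orthogonal trabecular rod lattice. The geometry is a deliberate stand-in for
# the distal radius that exposes both compartments and a surface-rich
# trabecular network at HRpQCT voxel size.

#' Phantom configuration
#'
#' @param grid_shape Voxels per axis (axial, row, column).
#' @param voxel_size_mm Isotropic voxel size (default 0.0607 mm).
#' @param cortex_outer_radius_mm,cortex_thickness_mm Shell geometry.
#' @param trabecular_rod_spacing_mm,trabecular_rod_thickness_mm Rod lattice
#'   geometry inside the shell.
#' @param ellipticity Ratio of the short to the long cross-sectional
#'   semi-axis of the shell (radii are not circular in vivo; this also gives
#'   the registration a unique rotational optimum).
#' @param taper Fractional increase of the cross-section from the first to
#'   the last axial slice, emulating the metaphyseal flare.
#' @param rod_dropout Fraction of lattice rods randomly omitted, emulating
#'   the irregularity of a real trabecular network.
#' @param density_cortex,density_trabecular,density_background Densities in
#'   mg HA/cm^3; must satisfy cortex > trabecular > background.
#' @param surface_roughness_mm SD of the smooth radial perturbation applied
#'   to the periosteal and endosteal surfaces (waviness of real cortices);
#'   widens the partial-volume band around high thresholds.
#' @param cortex_texture_sd SD (mg HA/cm^3) of the smooth mineralization
#'   texture superimposed on the cortical shell. Real cortical bone is not
#'   uniformly mineralized; the low-density tail of this texture is what
#'   makes high-threshold cortical masks sensitive to acquisition noise.
#' @param texture_scale_voxels Correlation length of the texture field.
#' @param cortical_porosity Volume fraction of the shell occupied by
#'   intracortical pores (small background-density cavities fully interior
#'   to the shell); distal-radius cortical porosity is a few percent.
#' @param pore_radius_voxels Chebyshev radius of each pore (1 = 3x3x3).
#' @param fracture_gap_slices Number of central axial slices over which the
#'   cortical shell is interrupted (density set to background), emulating a
#'   fracture gap. 0 = intact bone.
#' @param seed Integer seed (the phantom itself is deterministic; the seed
#'   anchors derived random streams).
#' @return A `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(128, 128, 128),
                           voxel_size_mm = 0.0607,
                           cortex_outer_radius_mm = 3.0,
                           cortex_thickness_mm = 0.8,
                           trabecular_rod_spacing_mm = 0.6,
                           trabecular_rod_thickness_mm = 0.24,
                           ellipticity = 0.85,
                           taper = 0.08,
                           rod_dropout = 0.3,
                           surface_roughness_mm = 0,
                           cortex_texture_sd = 120,
                           texture_scale_voxels = 3,
                           density_cortex = 900,
                           density_trabecular = 400,
                           density_background = 0,
                           cortical_porosity = 0.06,
                           pore_radius_voxels = 1L,
                           fracture_gap_slices = 0L,
                           seed = 1L) {
  if (cortex_thickness_mm >= cortex_outer_radius_mm)
    abort("cortex thickness must be smaller than its outer radius")
  if (!(density_cortex > density_trabecular &&
        density_trabecular > density_background))
    abort("densities must satisfy cortex > trabecular > background")
  if (min(density_cortex, density_trabecular, density_background) < 0)
    abort("densities must be >= 0")
  if (fracture_gap_slices < 0) abort("fracture_gap_slices must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 cortex_outer_radius_mm = cortex_outer_radius_mm,
                 cortex_thickness_mm = cortex_thickness_mm,
                 trabecular_rod_spacing_mm = trabecular_rod_spacing_mm,
                 trabecular_rod_thickness_mm = trabecular_rod_thickness_mm,
                 ellipticity = ellipticity,
                 taper = taper,
                 rod_dropout = rod_dropout,
                 density_cortex = density_cortex,
                 density_trabecular = density_trabecular,
                 density_background = density_background,
                 surface_roughness_mm = surface_roughness_mm,
                 cortex_texture_sd = cortex_texture_sd,
                 texture_scale_voxels = texture_scale_voxels,
                 cortical_porosity = cortical_porosity,
                 pore_radius_voxels = as.integer(pore_radius_voxels),
                 fracture_gap_slices = as.integer(fracture_gap_slices),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate the noise-free density phantom and its ground-truth region mask
#'
#' The cortical label is exactly the shell voxels (voxel centers with radial
#' distance in (inner, outer]); the trabecular region is the entire shell
#' interior, within which the rod lattice carries trabecular bone density and
#' the marrow the background density. Deterministic.
#'
#' @param config A [phantom_config()].
#' @return List with `volume` ([density_volume()]) and `mask`
#'   ([region_mask()]).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  vox <- config$voxel_size_mm
  ro <- config$cortex_outer_radius_mm
  ri <- ro - config$cortex_thickness_mm
  if (2 * ro >= min(d[2], d[3]) * vox)
    abort("grid too small to contain the cortical shell")
  cy <- (d[2] - 1) / 2 * vox
  cz <- (d[3] - 1) / 2 * vox
  y <- (seq_len(d[2]) - 1) * vox - cy
  z <- (seq_len(d[3]) - 1) * vox - cz
  x <- (seq_len(d[1]) - 1) * vox

  # elliptical, axially tapered cross-section: semi-axes grow linearly by
  # `taper` from the first to the last slice; short axis = ellipticity * long
  xfrac <- if (d[1] > 1) (seq_len(d[1]) - 1) / (d[1] - 1) else 0.5
  scale_x <- 1 + config$taper * (xfrac - 0.5)
  # smooth radial perturbation fields for the two surfaces
  rough_o <- rough_i <- 0
  if (config$surface_roughness_mm > 0) {
    set.seed(config$seed + 4L)
    smooth_field <- function() {
      f <- array(stats::rnorm(prod(d)), dim = d)
      f <- array(cpp_gauss3(f, array(TRUE, d), d, 4, 4L), d)
      f / stats::sd(f) * config$surface_roughness_mm
    }
    rough_o <- smooth_field()
    rough_i <- smooth_field()
  }
  ell <- function(a, b) sqrt(outer(y^2 / a^2, z^2 / b^2, `+`))
  shell <- array(FALSE, d); inner <- array(FALSE, d)
  for (i in seq_len(d[1])) {
    a_o <- ro * scale_x[i]; b_o <- config$ellipticity * a_o
    a_i <- a_o - config$cortex_thickness_mm
    b_i <- b_o - config$cortex_thickness_mm
    ro_pert <- if (is.array(rough_o)) rough_o[i, , ] / a_o else 0
    ri_pert <- if (is.array(rough_i)) rough_i[i, , ] / a_i else 0
    e_o <- ell(a_o, b_o) <= 1 + ro_pert
    e_i <- ell(a_i, b_i) <= 1 + ri_pert
    shell[i, , ] <- e_o & !e_i
    inner[i, , ] <- e_i
  }
  inner <- inner & shell == FALSE  # perturbations keep regions disjoint

  # rod lattice with random dropout: a voxel is rod if at least two of its
  # three coordinates lie within half a rod thickness of a lattice plane and
  # that rod was not dropped
  s <- config$trabecular_rod_spacing_mm
  hw <- config$trabecular_rod_thickness_mm / 2
  near_plane <- function(coord) abs((coord + s / 2) %% s - s / 2) <= hw
  plane_id <- function(coord) floor((coord + s / 2) / s)
  fx <- near_plane(x); fy <- near_plane(y + cy); fz <- near_plane(z + cz)
  px <- plane_id(x); py <- plane_id(y + cy); pz <- plane_id(z + cz)
  nx <- array(fx, dim = d)
  ny <- array(rep(fy, each = d[1]), dim = d)
  nz <- array(rep(fz, each = d[1] * d[2]), dim = d)
  set.seed(config$seed + 1L)
  # rods along axis 1 are indexed by their (y, z) lattice planes, etc.
  g_yz <- matrix(stats::runif((max(py) + 2) * (max(pz) + 2)) >= config$rod_dropout,
                 max(py) + 2, max(pz) + 2)
  g_xz <- matrix(stats::runif((max(px) + 2) * (max(pz) + 2)) >= config$rod_dropout,
                 max(px) + 2, max(pz) + 2)
  g_xy <- matrix(stats::runif((max(px) + 2) * (max(py) + 2)) >= config$rod_dropout,
                 max(px) + 2, max(py) + 2)
  idx_y <- array(rep(py + 1L, each = d[1]), dim = d)
  idx_z <- array(rep(pz + 1L, each = d[1] * d[2]), dim = d)
  idx_x <- array(px + 1L, dim = d)
  rod_x <- ny & nz & array(g_yz[cbind(as.vector(idx_y), as.vector(idx_z))], d)
  rod_y <- nx & nz & array(g_xz[cbind(as.vector(idx_x), as.vector(idx_z))], d)
  rod_z <- nx & ny & array(g_xy[cbind(as.vector(idx_x), as.vector(idx_y))], d)
  rods <- rod_x | rod_y | rod_z

  data <- array(config$density_background, dim = d)
  data[shell] <- config$density_cortex
  data[inner & rods] <- config$density_trabecular

  # smooth mineralization texture on the cortex: iid Gaussian field smoothed
  # to the requested correlation length, renormalized to the requested SD
  if (config$cortex_texture_sd > 0) {
    set.seed(config$seed + 3L)
    fld <- array(stats::rnorm(prod(d)), dim = d)
    sc <- config$texture_scale_voxels
    fld <- array(cpp_gauss3(fld, array(TRUE, d), d, sc, as.integer(sc)), d)
    fld <- fld / stats::sd(fld) * config$cortex_texture_sd
    # clamped above the cortical segmentation threshold so the shell stays a
    # single high-density component
    floor_d <- (config$density_cortex + config$density_trabecular) / 2.6
    data[shell] <- pmax(data[shell] + fld[shell], floor_d)
  }

  # intracortical pores: small cavities strictly interior to the shell (kept
  # clear of both surfaces so the closing step of the cortical split absorbs
  # them exactly); deterministic given the seed
  if (config$cortical_porosity > 0) {
    pr <- config$pore_radius_voxels
    deep <- array(cpp_morph_box(shell, d, pr + 2L, FALSE), d)
    deep[c(seq_len(pr + 1), d[1] - seq_len(pr + 1) + 1), , ] <- FALSE
    pore_vol <- (2 * pr + 1)^3
    n_pores <- round(config$cortical_porosity * sum(shell) / pore_vol)
    set.seed(config$seed + 2L)
    centers <- sample(which(deep), min(n_pores, sum(deep)))
    ci <- (centers - 1) %% d[1]
    cj <- ((centers - 1) %/% d[1]) %% d[2]
    ck <- (centers - 1) %/% (d[1] * d[2])
    for (p in seq_along(centers)) {
      ii <- (ci[p] - pr):(ci[p] + pr) + 1L
      jj <- (cj[p] - pr):(cj[p] + pr) + 1L
      kk <- (ck[p] - pr):(ck[p] + pr) + 1L
      data[ii, jj, kk] <- config$density_background
    }
  }

  fracture <- array(FALSE, dim = d)
  if (config$fracture_gap_slices > 0) {
    mid <- floor(d[1] / 2)
    from <- mid - floor(config$fracture_gap_slices / 2)
    rows <- from + seq_len(config$fracture_gap_slices)
    rows <- rows[rows >= 1 & rows <= d[1]]
    gap <- array(FALSE, dim = d); gap[rows, , ] <- TRUE
    data[gap & shell] <- config$density_background
    fracture[rows, , ] <- TRUE
  }

  labels <- array(0L, dim = d)
  labels[inner] <- 2L
  labels[shell] <- 1L
  list(volume = density_volume(data, voxel_size_mm = vox),
       mask = region_mask(labels, fracture = fracture,
                          provenance = "phantom ground truth"))
}
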