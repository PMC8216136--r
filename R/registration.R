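# Rigid pyramid registration.
#
# Similarity metric: normalized cross-correlation of densities over sample
# points drawn from the fixed image's dilated bone mask (robust to the global
# mean shift seen in casted acquisitions). Optimizer: Nelder-Mead over the 6
# rigid parameters, run coarse-to-fine over a Gaussian pyramid. The moving
# session is resampled exactly once, with the final transform, before any
# filtering or thresholding.

#' Rigidly register a moving volume to a fixed volume (pyramid approach)
#'
#' Multiresolution (coarse-to-fine) maximization of normalized
#' cross-correlation over the 6 rigid parameters. The returned transform maps
#' moving physical coordinates into fixed physical coordinates. The rotation
#' center defaults to the bone-mask centroid of the fixed image.
#'
#' @param moving,fixed [density_volume()] objects on grids with equal voxel
#'   size.
#' @param levels Number of pyramid levels (downsampling factor 2 per level).
#' @param init Optional initial [rigid_transform()].
#' @param bone_threshold Density (mg HA/cm^3) defining the bone mask from
#'   which metric sample points are drawn.
#' @param max_points Cap on metric sample points per level.
#' @param maxit Nelder-Mead iteration cap per level (recycled).
#' @param search_range_mm Half-width of the deterministic translation grid
#'   searched at the coarsest level (guards against lattice-period aliasing).
#' @param search_range_deg Half-width of the axis-wise rotation sweep at the
#'   mid pyramid level.
#' @param fix_rotation Optimize translations only, keeping the initial
#'   rotation (used for ladder rungs, whose rotation is inherited from the
#'   anchor stack).
#' @return List with `transform` ([rigid_transform()]) and `report` (list:
#'   `metric` final NCC, `iterations` per level, `converged`, `levels`).
#' @export
register_rigid_pyramid <- function(moving, fixed, levels = 3, init = NULL,
                                   bone_threshold = 200, max_points = 12000,
                                   maxit = c(400, 300, 250),
                                   search_range_mm = 12 * 0.0607,
                                   search_range_deg = 10,
                                   fix_rotation = FALSE) {
  stopifnot(inherits(moving, "density_volume"), inherits(fixed, "density_volume"))
  if (abs(moving$voxel_size_mm - fixed$voxel_size_mm) > 1e-9)
    abort("moving and fixed volumes must share the voxel size")
  maxit <- rep_len(maxit, levels)

  fpyr <- build_pyramid(fixed, levels)
  mpyr <- build_pyramid(moving, levels)
  # mild smoothing of the finest level symmetrizes interpolation blur between
  # the sharp fixed image and the once-resampled moving image; without it the
  # NCC optimum sits a fraction of a voxel away from the true alignment
  soften <- function(v) {
    v$data <- array(cpp_gauss3(v$data, v$valid, dim(v$data), 0.6, 1L),
                    dim(v$data))
    v
  }
  fpyr[[1]] <- soften(fpyr[[1]])
  mpyr[[1]] <- soften(mpyr[[1]])

  # rotation center: bone centroid of the fixed image (physical mm)
  bone <- fixed$data >= bone_threshold & fixed$valid
  if (!any(bone)) abort("no bone above `bone_threshold` in fixed volume")
  center <- bone_centroid(fixed, bone)

  par <- if (is.null(init)) rep(0, 6)
         else c(init$rotation_deg, init$translation_mm +
                  as.numeric(rot_matrix(init$rotation_deg) %*%
                               (center - init$center_mm)) -
                  (center - init$center_mm))
  # note: re-centering an initial transform keeps the same physical map

  iters <- integer(levels)
  conv <- TRUE
  value <- NA_real_
  # several candidate parameter vectors survive the coarse levels: periodic
  # structures (trabecular lattices) alias the metric, so a single descent
  # can lock onto a lattice-shifted optimum
  cands <- list(par)
  keep_n <- pmin(2^(seq_len(levels) - 1), 4)  # keep_n[lev]: 1 at finest
  for (lev in seq(levels, 1)) {
    f <- fpyr[[lev]]; m <- mpyr[[lev]]
    sp <- metric_points(f, bone_threshold, max_points)
    if (nrow(sp$pts) < 50) next
    obj <- function(p) {
      af <- rt_affine(rigid_transform(p[1:3], p[4:6], center))
      Mi <- t(af$M); bi <- -as.numeric(Mi %*% af$d)
      r <- cpp_ncc_points(m$data, m$valid, dim(m$data), vol_origin2(m),
                          m$voxel_size_mm, sp$pts, sp$vals, Mi, bi)
      if (r[2] < 0.25 * nrow(sp$pts)) return(1)  # overlap lost
      -r[1]
    }
    if (lev == levels && is.null(init)) {
      # deterministic translation grid; the best few cells seed candidates
      steps <- seq(-search_range_mm, search_range_mm, by = m$voxel_size_mm)
      grid <- as.matrix(expand.grid(steps, steps, steps))
      vals <- apply(grid, 1, function(g) obj(c(par[1:3], par[4:6] + g)))
      best <- order(vals)[seq_len(min(6, nrow(grid)))]
      cands <- lapply(best, function(b) c(par[1:3], par[4:6] + grid[b, ]))
      iters[lev] <- iters[lev] + nrow(grid)
    }
    if (lev == min(2, levels) && is.null(init)) {
      # axis-wise rotation sweep per candidate at the mid level, where
      # rod-scale structure reappears but the basin is still wide
      cands <- lapply(cands, function(pc) {
        for (axis in 1:3) {
          cand <- pc[axis] + seq(-search_range_deg, search_range_deg, by = 2)
          vals <- vapply(cand, function(a) {
            p2 <- pc; p2[axis] <- a; obj(p2)
          }, numeric(1))
          pc[axis] <- cand[which.min(vals)]
          iters[lev] <<- iters[lev] + length(cand)
        }
        pc
      })
    }
    scale_ang <- max(0.25, 2^(lev - 1)) * 2
    scale_trn <- m$voxel_size_mm * max(0.5, 2^(lev - 1)) * 4
    if (!is.null(init)) {   # polishing a propagated solution: stay local
      scale_ang <- scale_ang / 4
      scale_trn <- scale_trn / 4
    }
    scores <- numeric(length(cands))
    for (ci in seq_along(cands)) {
      pc <- cands[[ci]]
      for (pass in 1:2) {
        ps <- c(rep(scale_ang, 3), rep(scale_trn, 3)) / pass^2
        if (fix_rotation) {
          rot <- pc[1:3]
          fit <- optim(pc[4:6], function(tp) obj(c(rot, tp)),
                       method = "Nelder-Mead",
                       control = list(parscale = ps[4:6], maxit = maxit[lev],
                                      reltol = 1e-12))
          pc <- c(rot, fit$par)
        } else {
          fit <- optim(pc, obj, method = "Nelder-Mead",
                       control = list(parscale = ps, maxit = maxit[lev],
                                      reltol = 1e-12))
          pc <- fit$par
        }
        iters[lev] <- iters[lev] + fit$counts[1]
        if (lev == 1 && pass == 2 && fit$convergence != 0) conv <- FALSE
      }
      cands[[ci]] <- pc
      scores[ci] <- fit$value
    }
    ord <- order(scores)[seq_len(min(keep_n[lev], length(cands)))]
    cands <- cands[ord]
    value <- -min(scores)
  }
  par <- cands[[1]]
  list(transform = rigid_transform(par[1:3], par[4:6], center),
       report = list(metric = value, iterations = iters,
                     converged = conv, levels = levels))
}

bone_centroid <- function(vol, bone) {
  idx <- which(bone)
  d <- dim(vol$data)
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  vol_origin(vol) + vol$voxel_size_mm * c(mean(i), mean(j), mean(k))
}

build_pyramid <- function(vol, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- vol
  for (l in seq_len(levels - 1)) {
    v <- pyr[[l]]
    sm <- cpp_gauss3(v$data, v$valid, dim(v$data), sigma = 1, radius = 1)
    sm <- array(sm, dim = dim(v$data))
    d <- dim(sm)
    ix <- seq(1, d[1], by = 2); iy <- seq(1, d[2], by = 2); iz <- seq(1, d[3], by = 2)
    dv <- density_volume(sm[ix, iy, iz, drop = FALSE],
                         voxel_size_mm = v$voxel_size_mm * 2,
                         valid = v$valid[ix, iy, iz, drop = FALSE],
                         meta = v$meta)
    # keep the same physical origin: voxel (0,0,0) is shared
    dv$offset_slices <- 0L
    attr(dv, "origin_mm") <- vol_origin2(v)
    pyr[[l + 1]] <- dv
  }
  attr(pyr[[1]], "origin_mm") <- vol_origin(vol)
  pyr
}

vol_origin2 <- function(v) attr(v, "origin_mm") %||% vol_origin(v)

metric_points <- function(f, bone_threshold, max_points) {
  mask <- f$data >= bone_threshold & f$valid
  mask <- array(cpp_morph_box(mask, dim(f$data), 1L, TRUE), dim = dim(f$data))
  mask <- mask & f$valid
  idx <- which(mask)
  if (length(idx) > max_points)
    idx <- idx[unique(round(seq(1, length(idx), length.out = max_points)))]
  d <- dim(f$data)
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  org <- vol_origin2(f)
  pts <- cbind(org[1] + f$voxel_size_mm * i,
               org[2] + f$voxel_size_mm * j,
               org[3] + f$voxel_size_mm * k)
  list(pts = pts, vals = f$data[idx])
}

#' Resample a volume through a rigid transform
#'
#' Interpolation is trilinear for densities and nearest-neighbour for label
#' volumes. The validity mask of the output is FALSE wherever the source grid
#' was exited (or an invalid source voxel would have contributed).
#'
#' @param volume Moving [density_volume()].
#' @param transform [rigid_transform()] mapping moving into target physical
#'   space.
#' @param target A [density_volume()] defining the output grid (defaults to
#'   the moving volume's own grid).
#' @param nearest Use nearest-neighbour interpolation (for labels).
#' @return A [density_volume()] on the target grid.
#' @export
resample <- function(volume, transform, target = NULL, nearest = FALSE) {
  stopifnot(inherits(volume, "density_volume"))
  if (is.null(target)) target <- volume
  if (is_identity_transform(transform) &&
      identical(dim(volume$data), dim(target$data)) &&
      volume$offset_slices == target$offset_slices) {
    return(volume)
  }
  af <- rt_affine(transform)
  Mi <- t(af$M); bi <- -as.numeric(Mi %*% af$d)
  r <- cpp_resample_rigid(volume$data, volume$valid, dim(volume$data),
                          vol_origin(volume), dim(target$data),
                          vol_origin(target), volume$voxel_size_mm,
                          Mi, bi, nearest, 0)
  density_volume(array(r$data, dim = dim(target$data)),
                 voxel_size_mm = volume$voxel_size_mm,
                 offset_slices = target$offset_slices,
                 valid = array(r$valid, dim = dim(target$data)),
                 meta = volume$meta)
}

is_identity_transform <- function(tr) {
  all(abs(tr$rotation_deg) < 1e-12) && all(abs(tr$translation_mm) < 1e-12)
}

#' Ladder registration of multi-stack sessions
#'
#' Registers the axial stacks of session B to session A across a time
#' interval. The stack pair with the largest cross-time bone overlap (ties
#' broken toward the middle stack) is registered first; its solution is
#' propagated through the known reference-line offsets to initialize the
#' remaining stacks ("rungs"), which are then refined individually. Stacks
#' with no cross-time overlap are flagged unregistered.
#'
#' @param stacks_a,stacks_b Lists of [density_volume()] stacks (axial offsets
#'   in `offset_slices`), ordered distal to proximal.
#' @param ... Passed to [register_rigid_pyramid()].
#' @return List with `transforms` (per B stack; NULL if unregistered),
#'   `registered` logical vector, `fixed` and `moving` assembled
#'   [density_volume()] pair on session A's grid (moving resampled once), and
#'   `reports`.
#' @export
ladder_register_stacks <- function(stacks_a, stacks_b, ...) {
  asm_a <- assemble_stacks(stacks_a)
  nb <- length(stacks_b)
  overlaps <- vapply(stacks_b, function(sb) {
    lo <- max(sb$offset_slices, asm_a$offset_slices)
    hi <- min(sb$offset_slices + dim(sb$data)[1],
              asm_a$offset_slices + dim(asm_a$data)[1])
    max(0L, hi - lo)
  }, integer(1))
  ord <- order(-overlaps, abs(seq_len(nb) - (nb + 1) / 2))
  transforms <- vector("list", nb)
  reports <- vector("list", nb)
  registered <- rep(FALSE, nb)
  last_solution <- NULL
  for (s in ord) {
    if (overlaps[s] == 0L) next
    sb <- stacks_b[[s]]
    lv <- if (dim(sb$data)[1] < 32) 2 else 3   # thin stacks: shallower pyramid
    # non-anchor rungs inherit the arm's rotation from the anchor solution
    # (one limb, one rigid motion) and refine translation only, which a thin
    # stack determines well
    fit <- register_rigid_pyramid(sb, crop_axial(asm_a, sb, margin = 12),
                                  levels = lv, init = last_solution,
                                  fix_rotation = !is.null(last_solution), ...)
    transforms[[s]] <- fit$transform
    reports[[s]] <- fit$report
    registered[s] <- TRUE
    if (is.null(last_solution)) last_solution <- fit$transform
  }
  # assemble the registered moving stacks on A's grid (one resampling each)
  res_b <- vector("list", nb)
  for (s in seq_len(nb)) {
    if (!registered[s]) next
    res_b[[s]] <- resample(stacks_b[[s]], transforms[[s]], target = asm_a)
  }
  mov <- merge_resampled(res_b, asm_a)
  list(transforms = transforms, registered = registered,
       fixed = asm_a, moving = mov, reports = reports)
}

#' Assemble adjacent axial stacks into one volume
#'
#' Concatenates nonoverlapping stacks of one imaging session along the axial
#' axis using their reference-line offsets; slices covered by no stack are
#' marked invalid.
#'
#' @param stacks List of [density_volume()] stacks of one session.
#' @return A [density_volume()].
#' @export
assemble_stacks <- function(stacks) {
  if (length(stacks) == 1L) return(stacks[[1]])
  offs <- vapply(stacks, function(s) s$offset_slices, integer(1))
  ord <- order(offs)
  stacks <- stacks[ord]; offs <- offs[ord]
  lens <- vapply(stacks, function(s) dim(s$data)[1], integer(1))
  if (any(offs[-1] < (offs + lens)[-length(offs)]))
    abort("stacks overlap along the axial axis")
  d23 <- dim(stacks[[1]]$data)[2:3]
  lo <- offs[1]; hi <- max(offs + lens)
  n1 <- hi - lo
  data <- array(0, dim = c(n1, d23))
  valid <- array(FALSE, dim = c(n1, d23))
  for (s in seq_along(stacks)) {
    rows <- (offs[s] - lo) + seq_len(lens[s])
    data[rows, , ] <- stacks[[s]]$data
    valid[rows, , ] <- stacks[[s]]$valid
  }
  density_volume(data, stacks[[1]]$voxel_size_mm, offset_slices = lo,
                 valid = valid, meta = stacks[[1]]$meta)
}

crop_axial <- function(vol, ref, margin = 0L) {
  lo <- max(vol$offset_slices, ref$offset_slices - margin)
  hi <- min(vol$offset_slices + dim(vol$data)[1],
            ref$offset_slices + dim(ref$data)[1] + margin)
  rows <- (lo - vol$offset_slices) + seq_len(hi - lo)
  density_volume(vol$data[rows, , , drop = FALSE], vol$voxel_size_mm,
                 offset_slices = lo,
                 valid = vol$valid[rows, , , drop = FALSE], meta = vol$meta)
}

merge_resampled <- function(res_list, target) {
  data <- array(0, dim = dim(target$data))
  valid <- array(FALSE, dim = dim(target$data))
  for (r in res_list) {
    if (is.null(r)) next
    take <- r$valid & !valid
    data[take] <- r$data[take]
    valid <- valid | r$valid
  }
  density_volume(data, target$voxel_size_mm, target$offset_slices,
                 valid = valid, meta = res_list[[which(!vapply(res_list, is.null, TRUE))[1]]]$meta)
}

#' Common evaluation region of a registered session pair
#'
#' Remodeling is evaluated only where both sessions carry valid data, within
#' the union of the two periosteal contours (consistent with the additive
#' cortical rule, under which the trabecular region is the periosteal union
#' minus the cortical union).
#'
#' @param valid_a,valid_b Logical validity arrays on the shared grid.
#' @param periosteal_a,periosteal_b Logical periosteal masks.
#' @return Logical evaluation mask.
#' @export
common_region <- function(valid_a, valid_b, periosteal_a, periosteal_b) {
  stopifnot(identical(dim(valid_a), dim(valid_b)),
            identical(dim(valid_a), dim(periosteal_a)),
            identical(dim(valid_a), dim(periosteal_b)))
  out <- valid_a & valid_b & (periosteal_a | periosteal_b)
  if (!any(out)) abort("empty common evaluation region")
  out
}
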