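# Planted remodeling, simulated acquisition, and longitudinal study assembly.

#' Remodeling specification for the synthetic generator
#'
#' One row per (region, density threshold): target formation and resorption
#' volume fractions relative to the earlier session's bone at that threshold,
#' and the raw density assigned to newly formed voxels. Default magnitudes
#' follow the contralateral-radius reference values (trabecular 0.294/0.286
#' at 320 mg HA/cm^3; cortical 0.086/0.087 at 680 mg HA/cm^3).
#'
#' @param events Tibble with columns `region` ("cortical", "trabecular",
#'   "fracture", "intact"), `threshold`, `formation`, `resorption` (fractions
#'   in `[0, 1)`), and optionally `formation_density` (the raw density of
#'   newly formed voxels; defaults are high enough that the *filtered* value
#'   crosses the class threshold on an open surface).
#' @param surface_constrained Plant events on bone surfaces (26-neighbourhood
#'   adjacency to existing bone) rather than anywhere in the region.
#' @param packet_voxels Target size of one remodeling packet: events grow as
#'   compact clusters around sparse seeds (remodeling in vivo is organised in
#'   discrete packets, and isolated one-voxel events would not survive the
#'   partial-volume blur of resampling and filtering).
#' @param seed Integer seed for the planting order.
#' @return A `remodeling_spec`.
#' @export
remodeling_spec <- function(events = NULL, surface_constrained = TRUE,
                            packet_voxels = 64, seed = 1L) {
  if (is.null(events)) {
    events <- tibble(region = c("trabecular", "cortical"),
                     threshold = c(320, 680),
                     formation = c(0.294, 0.086),
                     resorption = c(0.286, 0.087),
                     formation_density = c(900, 1200))
  }
  events <- as_tibble(events)
  # newly formed bone must be dense enough that its *filtered* value crosses
  # the class threshold on an open surface under the 3^3 kernel (a half-space
  # retains ~52% of the raw density); defaults reflect that
  if (!"formation_density" %in% names(events))
    events$formation_density <- pmin(round(events$threshold * 2.2), 1200)
  if (any(events$formation < 0 | events$formation >= 1 |
          events$resorption < 0 | events$resorption >= 1))
    abort("formation/resorption fractions must be in [0, 1)")
  structure(list(events = events,
                 surface_constrained = isTRUE(surface_constrained),
                 packet_voxels = packet_voxels,
                 seed = as.integer(seed)),
            class = "remodeling_spec")
}

event_region_mask <- function(mask, region) {
  bone_region <- mask$labels > 0L
  switch(region,
         cortical = mask$labels == 1L,
         trabecular = mask$labels == 2L,
         fracture = bone_region & mask$fracture,
         intact = bone_region & !mask$fracture,
         abort(paste0("unknown region: ", region)))
}

#' Plant formation and resorption events into a volume
#'
#' Events are planted against the *filtered* representation of the volume
#' (the same constrained Gaussian the measurement applies), greedily and one
#' surface patch at a time, so that the planted voxel counts are exactly what
#' a threshold-difference measurement recovers on the noise-free, motion-free
#' pair. For each event the planted count is `round(fraction * N)` with `N`
#' the filtered bone voxel count of the region at that threshold in the input
#' volume. Formation is planted before resorption.
#'
#' @param volume [density_volume()] (noise-free).
#' @param mask [region_mask()] with ground-truth labels.
#' @param spec [remodeling_spec()].
#' @param schedule [threshold_schedule()]; all its thresholds are protected
#'   during planting so no out-of-class side effects occur.
#' @param filter [filter_params()] or NULL to plant against raw densities.
#' @param background_density Raw density assigned to resorbed voxels.
#' @return List with `volume` (the later session) and `truth`, a
#'   `ground_truth_remodeling` tibble with one row per (bone_type, partition,
#'   threshold): `earlier_voxels`, `formed_voxels`, `resorbed_voxels` plus
#'   list-columns of the planted voxel indices.
#' @export
apply_remodeling <- function(volume, mask, spec,
                             schedule = threshold_schedule(),
                             filter = filter_params(),
                             background_density = 0) {
  stopifnot(inherits(volume, "density_volume"), inherits(mask, "region_mask"),
            inherits(spec, "remodeling_spec"))
  d <- dim(volume$data)
  sigma <- if (is.null(filter)) 1 else filter$sigma
  radius <- if (is.null(filter)) 0L else filter_radius(filter)
  filt0 <- array(cpp_gauss3(volume$data, volume$valid, d, sigma, radius), d)
  raw <- volume$data
  filt <- filt0
  touched <- array(FALSE, d)
  set.seed(spec$seed)

  ev <- spec$events
  if (nrow(ev) > 30) abort("at most 30 planting events are supported")
  cell_zones <- lapply(ev$region, function(rg) event_region_mask(mask, rg))
  # protection zones follow the measurement cells: cortical apposition on the
  # outer surface is labeled cortical by the pairwise additive rule, so the
  # cortical zone carries a one-voxel outward halo
  prot_zones <- lapply(seq_len(nrow(ev)), function(i) {
    cell <- cell_zones[[i]]
    if (ev$region[i] == "trabecular") return(cell)
    halo <- array(cpp_morph_box(cell, d, 1L, TRUE), d) & mask$labels == 0L
    if (ev$region[i] %in% c("fracture", "intact")) {
      part <- if (ev$region[i] == "fracture") mask$fracture else !mask$fracture
      halo <- halo & part
    }
    cell | halo
  })
  protmask <- array(0L, d)
  for (i in seq_len(nrow(ev)))
    protmask <- protmask + bitwShiftL(1L, i - 1L) * prot_zones[[i]]

  planted_log <- list()
  plant_one <- function(event_i, frac, formation, new_density) {
    region_name <- ev$region[event_i]
    targetT <- ev$threshold[event_i]
    cell <- cell_zones[[event_i]]
    # candidate zone: formation may grow a one-voxel halo around the cortical
    # shell (the pairwise additive rule assigns such apposition to cortex);
    # trabecular formation stays inside the periosteal interior
    czone <- if (formation && region_name != "trabecular") {
      prot_zones[[event_i]]
    } else if (formation) {
      # dense new trabecular bone must stay clearly off the shell so the
      # closing step of the cortical split cannot absorb it into the cortex
      cell & !array(cpp_morph_box(mask$labels == 1L, d, 5L, TRUE), d)
    } else cell
    N <- sum(filt0 >= targetT & cell)
    n_target <- round(frac * N)
    if (n_target == 0) return(invisible(NULL))
    remaining <- n_target
    # remodeling is spatially clustered (discrete remodeling packets): grow
    # compact multi-voxel deposits/pits around sparse random seeds, so that
    # planted structures are thick enough to survive interpolation and
    # filtering. Each round restricts candidates to the neighborhood of this
    # event's existing packets; fresh seed batches are drawn when growth
    # stalls or packets saturate.
    evmask <- array(FALSE, d)
    n_seeds_batch <- max(1L, ceiling(n_target / spec$packet_voxels))
    fresh_seeds <- TRUE
    zero_rounds <- 0L
    rounds <- 0L
    repeat {
      rounds <- rounds + 1L
      if (rounds > 500L)
        abort(sprintf("infeasible %s in region '%s' at threshold %g: no progress after %d planting rounds (%d of %d events remaining)",
                      if (formation) "formation" else "resorption",
                      region_name, targetT, rounds - 1L, remaining, n_target))
      bone_now <- filt >= targetT
      if (formation) {
        cand <- czone & !bone_now & !touched
        if (spec$surface_constrained) {
          surf <- array(cpp_morph_box(bone_now & czone, d, 1L, TRUE), d)
          cand <- cand & surf
        }
      } else {
        cand <- czone & bone_now & !touched
        if (spec$surface_constrained) {
          notbone <- array(cpp_morph_box(!bone_now, d, 1L, TRUE), d)
          cand <- cand & notbone
        }
      }
      if (any(evmask)) {
        near <- array(cpp_morph_box(evmask, d, 1L, TRUE), d)
        grow <- cand & near
      } else grow <- cand & FALSE
      idx <- which(grow)
      if (fresh_seeds || length(idx) == 0) {
        pool <- which(cand & !grow)
        if (length(pool)) {
          seeds <- sample(pool, min(n_seeds_batch, length(pool)))
          idx <- c(idx, seeds)
        }
        fresh_seeds <- FALSE
      }
      if (length(idx) == 0)
        abort(sprintf("infeasible %s in region '%s' at threshold %g: no candidates with %d of %d events remaining",
                      if (formation) "formation" else "resorption",
                      region_name, targetT, remaining, n_target))
      idx <- sample(idx)
      res <- cpp_plant(raw, filt, d, ev$threshold, event_i - 1L, targetT,
                       as.integer(remaining), new_density, formation,
                       sigma, radius, as.integer(idx - 1L),
                       czone, protmask, touched, 9L)
      raw <<- array(res$vol, d)
      filt <<- array(res$filt, d)
      touched <<- array(res$touched, d)
      if (length(res$planted)) evmask[res$planted + 1L] <- TRUE
      key <- paste0(region_name, "_", targetT, "_",
                    if (formation) "F" else "R")
      planted_log[[key]] <<- c(planted_log[[key]], res$planted + 1L)
      prev_remaining <- remaining
      remaining <- remaining - res$n_planted
      if (remaining == 0) break
      if (res$n_planted == 0) {
        zero_rounds <- zero_rounds + 1L
        if (zero_rounds <= 20L) { fresh_seeds <- TRUE; next }
        abort(sprintf("infeasible %s in region '%s' at threshold %g: stalled with %d of %d events remaining",
                      if (formation) "formation" else "resorption",
                      region_name, targetT, remaining, n_target))
      }
      zero_rounds <- 0L
      if (res$n_planted < 0.05 * prev_remaining) fresh_seeds <- TRUE
    }
    invisible(NULL)
  }

  # formation first: it needs the sub-threshold surface band and the pore
  # system, which resorption would otherwise consume and lock (committed
  # voxels may not change state again)
  for (i in seq_len(nrow(ev)))
    plant_one(i, ev$formation[i], TRUE, ev$formation_density[i])
  for (i in seq_len(nrow(ev)))
    plant_one(i, ev$resorption[i], FALSE, background_density)

  later <- density_volume(raw, volume$voxel_size_mm, volume$offset_slices,
                          valid = volume$valid, meta = volume$meta)
  # ground truth is reported against the same masks the measurement builds:
  # per-session segmentation and the pairwise additive cortical rule
  mask_e <- split_cortical_trabecular(volume, periosteal_contour(volume))
  mask_l <- split_cortical_trabecular(later, periosteal_contour(later))
  mask_e$fracture <- mask$fracture; mask_l$fracture <- mask$fracture
  pair <- additive_cortical_mask(mask_e, mask_l)
  truth <- ground_truth_table(filt0, filt, pair, schedule)
  list(volume = later, truth = truth, planted = planted_log,
       filtered = list(earlier = filt0, later = filt))
}

# exact per-cell diff of the filtered noise-free volumes
ground_truth_table <- function(filt_earlier, filt_later, mask, schedule) {
  d <- dim(filt_earlier)
  partitions <- if (any(mask$fracture)) c("fracture", "intact") else "intact"
  rows <- list()
  for (bt in c("cortical", "trabecular")) {
    thr <- schedule_for(schedule, bt)
    for (fx in partitions) {
      sel <- region_select(mask, bt, fx)
      for (T in thr) {
        e <- filt_earlier >= T & sel
        l <- filt_later >= T & sel
        formed <- which(l & !e)
        resorbed <- which(e & !l)
        rows[[length(rows) + 1]] <- tibble(
          bone_type = bt, partition = fx, threshold = T,
          earlier_voxels = sum(e), formed_voxels = length(formed),
          resorbed_voxels = length(resorbed),
          formation_fraction = if (sum(e) > 0) length(formed) / sum(e) else NA_real_,
          resorption_fraction = if (sum(e) > 0) length(resorbed) / sum(e) else NA_real_,
          formed_idx = list(formed), resorbed_idx = list(resorbed))
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("ground_truth_remodeling", class(out))
  out
}

#' Acquisition specification
#'
#' Describes how one imaging session observes the underlying bone: the true
#' rigid motion of the arm relative to the reference frame, additive Gaussian
#' acquisition noise (inflated by `casted_factor` when imaging through a
#' cast, which raises soft-tissue noise SD while leaving the mean signal
#' unchanged), and the axial stack layout.
#'
#' @param true_transform [rigid_transform()] mapping the reference bone into
#'   this session's frame.
#' @param noise_sd Soft-tissue noise SD, mg HA/cm^3.
#' @param casted Imaging through a cast?
#' @param casted_factor Multiplier (> 1) on `noise_sd` when casted.
#' @param stack_lengths_slices,stack_offsets_slices Stack layout; must tile a
#'   sub-range of the axial extent without overlap, ordered proximally.
#' @param seed Integer seed for the noise stream.
#' @return An `acquisition_spec`.
#' @export
acquisition_spec <- function(true_transform = rigid_transform(),
                             noise_sd = 220, casted = FALSE,
                             casted_factor = 1.5,
                             stack_lengths_slices = NULL,
                             stack_offsets_slices = NULL,
                             seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (casted_factor <= 1) abort("casted_factor must be > 1")
  if (!is.null(stack_offsets_slices)) {
    o <- stack_offsets_slices; l <- stack_lengths_slices
    if (length(o) != length(l)) abort("stack offsets and lengths differ in length")
    if (is.unsorted(o)) abort("stacks must be ordered proximally")
    if (length(o) > 1 && any(o[-1] < (o + l)[-length(o)]))
      abort("stacks must not overlap")
  }
  structure(list(true_transform = true_transform, noise_sd = noise_sd,
                 casted = isTRUE(casted), casted_factor = casted_factor,
                 stack_lengths_slices = stack_lengths_slices,
                 stack_offsets_slices = stack_offsets_slices,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Simulate the acquisition of one imaging session
#'
#' Applies the session's rigid motion to the underlying volume, crops it into
#' axial stacks at the specified reference-line offsets, and adds Gaussian
#' acquisition noise (SD multiplied by `casted_factor` for casted sessions).
#' The validity mask of each stack marks voxels that stayed inside the source
#' during resampling. Deterministic given the spec's seed.
#'
#' @param volume The underlying noise-free [density_volume()].
#' @param spec An [acquisition_spec()].
#' @return List of [density_volume()] stacks.
#' @export
apply_acquisition <- function(volume, spec) {
  stopifnot(inherits(volume, "density_volume"),
            inherits(spec, "acquisition_spec"))
  d <- dim(volume$data)
  offs <- spec$stack_offsets_slices %||% volume$offset_slices
  lens <- spec$stack_lengths_slices %||% d[1]
  lo <- volume$offset_slices
  if (min(offs) < lo || max(offs + lens) > lo + d[1])
    abort("stack layout exceeds the volume's axial extent")
  identity_motion <- is_identity_transform(spec$true_transform)
  moved <- if (identity_motion) volume
           else resample(volume, spec$true_transform, target = volume)
  if (!identity_motion && !any(moved$valid & (moved$data >= 200)))
    abort("transform moved the bone outside the grid")
  sd_eff <- spec$noise_sd * if (spec$casted) spec$casted_factor else 1
  set.seed(spec$seed)
  purrr::map2(offs, lens, function(o, l) {
    rows <- (o - lo) + seq_len(l)
    data <- moved$data[rows, , , drop = FALSE]
    if (sd_eff > 0) data <- data + array(rnorm(length(data), 0, sd_eff),
                                         dim = dim(data))
    density_volume(data, volume$voxel_size_mm, offset_slices = o,
                   valid = moved$valid[rows, , , drop = FALSE],
                   meta = c(volume$meta,
                            list(casted = spec$casted,
                                 noise_sd = sd_eff)))
  })
}

#' Build a longitudinal synthetic study
#'
#' Generates the phantom, applies per-interval remodeling cumulatively, and
#' simulates each session's acquisition (motion, stacks, noise). The study
#' default mirrors the clinical design: six sessions labeled W1, W3, W5, M3,
#' M6, M12, the first two casted, three axial stacks per session. Interval
#' records are keyed by the earlier session (a W1 row describes W1 relative
#' to W3).
#'
#' @param config [phantom_config()].
#' @param specs A single [remodeling_spec()] (recycled) or a list with one
#'   spec per interval (`n_sessions - 1`).
#' @param acquisitions Optional list of [acquisition_spec()], one per
#'   session; defaults to random small rigid motions (<= 2 deg, ~3 voxels),
#'   the default noise level, and casted flags for the first two sessions.
#' @param n_sessions Number of imaging sessions (>= 2).
#' @param n_stacks Stacks per session for the default layout.
#' @param noise_sd Default acquisition noise SD (mg HA/cm^3); the default
#'   220 reproduces the contralateral-radius apparent trabecular remodeling
#'   fractions on the default phantom.
#' @param seed Master seed; per-operation streams are derived from it.
#' @return List with `sessions` (list of stack lists), `truth_volumes`
#'   (noise-free per-session volumes), `mask` (phantom region mask),
#'   `ground_truth` (per-interval tibble), `true_transforms`, `manifest`
#'   (sessions/stacks tibbles) and `config`.
#' @export
make_longitudinal_study <- function(config = phantom_config(),
                                    specs = remodeling_spec(),
                                    acquisitions = NULL,
                                    n_sessions = 6, n_stacks = 3,
                                    noise_sd = 220, seed = 1L) {
  if (n_sessions < 2) abort("n_sessions must be >= 2")
  session_labels <- c("W1", "W3", "W5", "M3", "M6", "M12")
  if (n_sessions > length(session_labels))
    session_labels <- c(session_labels,
                        paste0("S", seq_len(n_sessions - length(session_labels)) + 6))
  labels <- session_labels[seq_len(n_sessions)]
  if (inherits(specs, "remodeling_spec"))
    specs <- rep(list(specs), n_sessions - 1)
  if (length(specs) != n_sessions - 1)
    abort("`specs` must have one remodeling spec per interval (n_sessions - 1)")

  ph <- generate_phantom(config)
  d <- config$grid_shape
  if (is.null(acquisitions)) {
    set.seed(seed)
    acquisitions <- lapply(seq_len(n_sessions), function(t) {
      casted <- t <= 2 && n_sessions >= 6
      tr <- if (t == 1) rigid_transform() else
        rigid_transform(rotation_deg = stats::runif(3, -2, 2),
                        translation_mm = stats::runif(3, -0.2, 0.2),
                        center_mm = rep((d[1] - 1) / 2 * config$voxel_size_mm, 3))
      len <- floor(d[1] / n_stacks)
      offs <- (seq_len(n_stacks) - 1) * len
      acquisition_spec(true_transform = tr, noise_sd = noise_sd,
                       casted = casted,
                       stack_lengths_slices = rep(len, n_stacks),
                       stack_offsets_slices = offs,
                       seed = seed + 7919L * t)
    })
  }
  if (length(acquisitions) != n_sessions)
    abort("`acquisitions` must have one spec per session")

  truth_volumes <- vector("list", n_sessions)
  truth_volumes[[1]] <- ph$volume
  gts <- vector("list", n_sessions - 1)
  for (t in seq_len(n_sessions - 1)) {
    sp <- specs[[t]]
    sp$seed <- sp$seed + 104729L * t
    r <- apply_remodeling(truth_volumes[[t]], ph$mask, sp)
    truth_volumes[[t + 1]] <- r$volume
    gts[[t]] <- mutate(r$truth, interval = labels[t], .before = 1)
  }
  ground_truth <- bind_rows(gts)

  sessions <- vector("list", n_sessions)
  for (t in seq_len(n_sessions)) {
    v <- truth_volumes[[t]]
    v$meta <- list(session = labels[t], arm = "fractured",
                   vgs = if (acquisitions[[t]]$casted) 2L else 1L)
    sessions[[t]] <- apply_acquisition(v, acquisitions[[t]])
  }

  manifest_sessions <- tibble(
    session = labels, time_index = seq_len(n_sessions),
    arm = "fractured",
    casted = vapply(acquisitions, function(a) a$casted, logical(1)),
    vgs = vapply(acquisitions, function(a) if (a$casted) 2L else 1L, integer(1)))
  manifest_stacks <- purrr::map_dfr(seq_len(n_sessions), function(t) {
    purrr::map_dfr(sessions[[t]], function(st) {
      tibble(session = labels[t],
             file = sprintf("%s_stack%03d.mha", labels[t], st$offset_slices),
             offset_slices = st$offset_slices, n_slices = dim(st$data)[1])
    })
  })

  list(sessions = sessions, truth_volumes = truth_volumes, mask = ph$mask,
       ground_truth = ground_truth,
       true_transforms = lapply(acquisitions, function(a) a$true_transform),
       manifest = list(sessions = manifest_sessions, stacks = manifest_stacks,
                       fracture_slices = NULL,
                       voxel_size_mm = config$voxel_size_mm),
       config = config, labels = labels)
}
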