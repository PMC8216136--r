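# The analysis core: constrained Gaussian filtering, multidensity
# thresholding, formation/resorption volume fractions, central-slice bone
# profiles, BST-SNR, and the thresholded-difference comparator.

#' Multidensity threshold schedule
#'
#' Densities from 200 to 920 mg HA/cm^3 in steps of 120. All thresholds apply
#' to the cortical region; the trabecular region uses only 200-680, below
#' which essentially all trabecular bone volume lies.
#'
#' @param densities Strictly increasing densities (mg HA/cm^3).
#' @param trabecular_max Highest threshold evaluated for trabecular bone.
#' @return A `threshold_schedule`.
#' @export
threshold_schedule <- function(densities = seq(200, 920, by = 120),
                               trabecular_max = 680) {
  if (is.unsorted(densities, strictly = TRUE))
    abort("thresholds must be strictly increasing")
  structure(list(densities = densities, trabecular_max = trabecular_max),
            class = "threshold_schedule")
}

schedule_for <- function(schedule, bone_type) {
  if (bone_type == "trabecular")
    schedule$densities[schedule$densities <= schedule$trabecular_max]
  else schedule$densities
}

#' Constrained Gaussian filter parameters
#'
#' The filter is a Gaussian of width `sigma` truncated to a cube of
#' half-width `min(ceiling(truncate * sigma), support)` voxels with its
#' weights renormalized to sum to one; at volume boundaries and next to
#' invalid voxels the weights are renormalized over the remaining valid
#' neighborhood so nothing spills in from missing data. With the defaults
#' (sigma 0.8, truncate 1.25, support 1.0) the kernel is 3 x 3 x 3.
#'
#' @param sigma Gaussian width in voxels.
#' @param truncate Truncation multiple of sigma.
#' @param support Maximum kernel half-width in voxels.
#' @return A `filter_params`.
#' @export
filter_params <- function(sigma = 0.8, truncate = 1.25, support = 1.0) {
  if (min(sigma, truncate, support) <= 0)
    abort("sigma, truncate and support must all be > 0")
  if (support < 1) abort("support below one voxel leaves no kernel")
  structure(list(sigma = sigma, truncate = truncate, support = support),
            class = "filter_params")
}

filter_radius <- function(fp) as.integer(min(ceiling(fp$truncate * fp$sigma),
                                             fp$support))

#' Apply the constrained Gaussian filter
#'
#' @param volume [density_volume()].
#' @param params [filter_params()].
#' @return Filtered [density_volume()] (validity unchanged).
#' @export
constrained_gaussian_filter <- function(volume, params = filter_params()) {
  stopifnot(inherits(volume, "density_volume"))
  d <- dim(volume$data)
  out <- cpp_gauss3(volume$data, volume$valid, d, params$sigma,
                    filter_radius(params))
  volume$data <- array(out, d)
  volume
}

# closed-form truncated normalized kernel (used by tests as the reference)
gaussian_kernel_3d <- function(sigma = 0.8, radius = 1L) {
  off <- seq(-radius, radius)
  g <- expand.grid(off, off, off)
  w <- exp(-0.5 * rowSums(g^2) / sigma^2)
  array(w / sum(w), dim = rep(2 * radius + 1, 3))
}

#' Binarize a volume at a density threshold
#'
#' A voxel is bone at threshold T iff its density is >= T (inclusive) and the
#' voxel is valid.
#'
#' @param volume [density_volume()].
#' @param density Threshold in mg HA/cm^3.
#' @return Logical array.
#' @export
threshold_volume <- function(volume, density) {
  volume$data >= density & volume$valid
}

#' Formation and resorption volume fractions across a threshold schedule
#'
#' For each applicable threshold T: formation voxels are in the later image's
#' bone but not the earlier's; resorption voxels are in the earlier but not
#' the later; fractions divide by the earlier session's bone voxel count at
#' T. Counts obey the conservation identity
#' later = earlier + formed - resorbed exactly. Cells with an empty earlier
#' bone mask report NA fractions (flagged, never coerced to zero).
#'
#' @param earlier,later Filtered, registered [density_volume()] objects on a
#'   common grid.
#' @param mask [region_mask()] (typically the pairwise additive mask).
#' @param eval_mask Logical array restricting evaluation (validity
#'   intersection from [common_region()]); default all TRUE.
#' @param schedule [threshold_schedule()].
#' @param interval Interval label (keyed by the earlier session).
#' @return A `remodeling_result` tibble: one row per (bone_type, partition,
#'   threshold) with counts and fractions.
#' @export
formation_resorption <- function(earlier, later, mask, eval_mask = NULL,
                                 schedule = threshold_schedule(),
                                 interval = NA_character_) {
  d <- dim(earlier$data)
  if (!identical(d, dim(later$data))) abort("volumes must share the grid")
  if (is.null(eval_mask)) eval_mask <- array(TRUE, d)
  partitions <- if (any(mask$fracture)) c("fracture", "intact") else "intact"
  rows <- list()
  for (bt in c("cortical", "trabecular")) {
    for (fx in partitions) {
      sel <- region_select(mask, bt, fx) & eval_mask
      for (T in schedule_for(schedule, bt)) {
        e <- threshold_volume(earlier, T) & sel
        l <- threshold_volume(later, T) & sel
        ne <- sum(e)
        formed <- sum(l & !e)
        resorbed <- sum(e & !l)
        rows[[length(rows) + 1]] <- tibble(
          interval = interval, bone_type = bt, partition = fx, threshold = T,
          earlier_voxels = ne, formed_voxels = formed,
          resorbed_voxels = resorbed,
          formation_fraction = if (ne > 0) formed / ne else NA_real_,
          resorption_fraction = if (ne > 0) resorbed / ne else NA_real_,
          method = "multidensity")
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("remodeling_result", class(out))
  out
}

#' Central-slice bone volume profile
#'
#' Bone voxels at each threshold are summed over the single central axial
#' slice (index floor(n/2), 0-based) of the analyzed volume and converted to
#' volumes, profiling the density distribution of each region.
#'
#' @param volume Filtered [density_volume()].
#' @param mask [region_mask()].
#' @param schedule [threshold_schedule()].
#' @return Tibble: bone_type, threshold, voxel count and volume (mm^3).
#' @export
central_slice_volumes <- function(volume, mask,
                                  schedule = threshold_schedule()) {
  d <- dim(volume$data)
  ctr <- floor(d[1] / 2) + 1L  # floor(n/2) in 0-based indexing
  rows <- list()
  for (bt in c("cortical", "trabecular")) {
    sel <- region_select(mask, bt, "all")
    for (T in schedule_for(schedule, bt)) {
      cnt <- sum(volume$data[ctr, , ] >= T & volume$valid[ctr, , ] &
                   sel[ctr, , ])
      rows[[length(rows) + 1]] <- tibble(
        bone_type = bt, threshold = T, voxels = cnt,
        volume_mm3 = cnt * volume$voxel_size_mm^3)
    }
  }
  bind_rows(rows)
}

#' Bone-to-soft-tissue signal-to-noise ratio
#'
#' BST-SNR is the mean mineralized density within the cortical mask divided
#' by the SD of densities in the region immediately surrounding the radius
#' (a ring of `ring_width` voxels outside the periosteal contour).
#'
#' @param volume [density_volume()].
#' @param cortical_mask,periosteal_mask Logical arrays.
#' @param ring_width Width of the surrounding ring in voxels.
#' @return A one-row tibble: cortical_mean, surround_sd, bst_snr.
#' @export
bst_snr <- function(volume, cortical_mask, periosteal_mask, ring_width = 5) {
  d <- dim(volume$data)
  if (!any(cortical_mask)) abort("empty cortical mask")
  ring <- array(cpp_morph_box(periosteal_mask, d, as.integer(ring_width),
                              TRUE), d) & !periosteal_mask & volume$valid
  if (sum(ring) < 2) abort("empty surround region")
  cm <- mean(volume$data[cortical_mask & volume$valid])
  ss <- sd(volume$data[ring])
  if (ss <= 0) abort("degenerate (zero-variance) surround region")
  tibble(cortical_mean = cm, surround_sd = ss, bst_snr = cm / ss)
}

#' Thresholded-difference remodeling (comparator method)
#'
#' The alternative quantification used by longitudinal HRpQCT studies of
#' intact bone: voxelwise density difference within the evaluation region,
#' candidate formation where the difference is >= `diff_threshold` (mg
#' HA/cm^3), resorption where <= -`diff_threshold`; connected clusters
#' smaller than `min_cluster` voxels are discarded as noise. Published
#' variants use 125/5 and 225/30 for the difference threshold and minimum
#' cluster size. Fractions divide by the evaluation-region voxel count
#' ("common volume", the convention of the studies that introduced the
#' method), or by the earlier bone voxel count at a base threshold per bone
#' type in "baseline_bone" mode.
#'
#' @param earlier,later Registered (optionally filtered) volumes on a common
#'   grid.
#' @param mask [region_mask()].
#' @param eval_mask Logical evaluation mask (default all TRUE).
#' @param diff_threshold Density difference threshold (mg HA/cm^3).
#' @param min_cluster Minimum surviving cluster size in voxels.
#' @param connectivity 26 (default) or 6.
#' @param base_thresholds Named vector of per-bone-type denominator
#'   thresholds.
#' @param denominator "baseline_bone" or "common_volume".
#' @param interval Interval label.
#' @return A `remodeling_result` tibble (method = "thresholded_diff").
#' @export
thresholded_difference_remodeling <- function(earlier, later, mask,
                                              eval_mask = NULL,
                                              diff_threshold = 125,
                                              min_cluster = 5,
                                              connectivity = 26,
                                              base_thresholds = c(trabecular = 320,
                                                                  cortical = 450),
                                              denominator = c("common_volume",
                                                              "baseline_bone"),
                                              interval = NA_character_) {
  denominator <- match.arg(denominator)
  d <- dim(earlier$data)
  if (is.null(eval_mask)) eval_mask <- array(TRUE, d)
  eval_mask <- eval_mask & earlier$valid & later$valid
  delta <- later$data - earlier$data
  keep_clusters <- function(cand) {
    if (min_cluster <= 1 || !any(cand)) return(cand)
    lab <- cpp_label3d(cand, d, as.integer(connectivity))
    sizes <- tabulate(lab)
    big <- which(sizes >= min_cluster)
    array(lab %in% big & lab > 0L, d)
  }
  form_all <- keep_clusters(delta >= diff_threshold & eval_mask)
  res_all <- keep_clusters(delta <= -diff_threshold & eval_mask)
  partitions <- if (any(mask$fracture)) c("fracture", "intact") else "intact"
  rows <- list()
  for (bt in c("cortical", "trabecular")) {
    for (fx in partitions) {
      sel <- region_select(mask, bt, fx) & eval_mask
      denom <- if (denominator == "baseline_bone")
        sum(threshold_volume(earlier, base_thresholds[[bt]]) & sel)
      else sum(sel)
      formed <- sum(form_all & sel)
      resorbed <- sum(res_all & sel)
      rows[[length(rows) + 1]] <- tibble(
        interval = interval, bone_type = bt, partition = fx,
        threshold = base_thresholds[[bt]],
        earlier_voxels = denom, formed_voxels = formed,
        resorbed_voxels = resorbed,
        formation_fraction = if (denom > 0) formed / denom else NA_real_,
        resorption_fraction = if (denom > 0) resorbed / denom else NA_real_,
        method = "thresholded_diff")
    }
  }
  out <- bind_rows(rows)
  attr(out, "denominator") <- denominator
  attr(out, "diff_threshold") <- diff_threshold
  attr(out, "min_cluster") <- min_cluster
  class(out) <- c("remodeling_result", class(out))
  out
}

#' Run the full per-interval analysis of a registered session pair
#'
#' Orchestrates one interval: constrained Gaussian filtering, segmentation
#' of both sessions, the additive pairwise mask, the common evaluation
#' region, formation/resorption across the threshold schedule (or the
#' thresholded-difference comparator), BST-SNR of both sessions and the
#' central-slice profiles.
#'
#' @param earlier,later Registered [density_volume()] pair on a common grid
#'   (unfiltered; filtering happens here).
#' @param interval Interval label (the earlier session's).
#' @param fracture_spec Fracture partition spec for [fracture_partition()].
#' @param schedule [threshold_schedule()].
#' @param filter [filter_params()].
#' @param method "multidensity" or "thresholded_diff".
#' @param masks Optional list(earlier=, later=) of precomputed
#'   [region_mask()] objects (skips segmentation).
#' @param ... Passed to [thresholded_difference_remodeling()].
#' @return List: `remodeling` (result tibble), `quality` (two-row BST-SNR
#'   tibble), `profiles` (central-slice tibble for both sessions), `mask`
#'   (pairwise region mask), `eval_mask`.
#' @export
run_interval <- function(earlier, later, interval = NA_character_,
                         fracture_spec = NULL,
                         schedule = threshold_schedule(),
                         filter = filter_params(),
                         method = c("multidensity", "thresholded_diff"),
                         masks = NULL, ...) {
  method <- match.arg(method)
  d <- dim(earlier$data)
  if (is.null(masks)) {
    peri_e <- periosteal_contour(earlier)
    peri_l <- periosteal_contour(later)
    mask_e <- split_cortical_trabecular(earlier, peri_e)
    mask_l <- split_cortical_trabecular(later, peri_l)
  } else {
    mask_e <- masks$earlier; mask_l <- masks$later
  }
  fx <- fracture_partition(d, fracture_spec)
  mask_e$fracture <- fx; mask_l$fracture <- fx
  pair_mask <- additive_cortical_mask(mask_e, mask_l)
  eval_mask <- common_region(earlier$valid, later$valid,
                             periosteal_of(mask_e), periosteal_of(mask_l))
  fe <- constrained_gaussian_filter(earlier, filter)
  fl <- constrained_gaussian_filter(later, filter)
  remodeling <- if (method == "multidensity")
    formation_resorption(fe, fl, pair_mask, eval_mask, schedule, interval)
  else
    thresholded_difference_remodeling(fe, fl, pair_mask, eval_mask,
                                      interval = interval, ...)
  snr_or_na <- function(vol, msk) {
    tryCatch(bst_snr(vol, msk$labels == 1L, periosteal_of(msk)),
             error = function(e) tibble(cortical_mean = NA_real_,
                                        surround_sd = NA_real_,
                                        bst_snr = NA_real_))
  }
  quality <- bind_rows(
    mutate(snr_or_na(earlier, mask_e), session = "earlier", .before = 1),
    mutate(snr_or_na(later, mask_l), session = "later", .before = 1))
  profiles <- bind_rows(
    mutate(central_slice_volumes(fe, mask_e, schedule), session = "earlier",
           .before = 1),
    mutate(central_slice_volumes(fl, mask_l, schedule), session = "later",
           .before = 1))
  list(remodeling = remodeling, quality = quality, profiles = profiles,
       mask = pair_mask, eval_mask = eval_mask)
}
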