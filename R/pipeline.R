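# Study-level orchestration: simulate -> analyze -> report. These functions
# (plus the thin Rscript front-end in inst/cli/) are the command-line surface
# of the package.

#' Simulate a longitudinal study to disk
#'
#' Generates a synthetic study with [make_longitudinal_study()] and writes
#' per-session stacks (MetaImage), the YAML manifest, the ground-truth CSV
#' and the true transforms into `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [make_longitudinal_study()].
#' @param seed Master seed.
#' @return The study bundle, invisibly; side effect: files under `out_dir`.
#' @export
simulate_study <- function(out_dir, ..., seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- make_longitudinal_study(..., seed = seed)
  message("simulate: writing ", nrow(study$manifest$stacks), " stacks to ",
          out_dir)
  for (t in seq_along(study$sessions)) {
    for (st in study$sessions[[t]]) {
      f <- sprintf("%s_stack%03d.mha", study$labels[t], st$offset_slices)
      write_volume(st, file.path(out_dir, f))
    }
  }
  write_manifest(study$manifest, file.path(out_dir, "manifest.yaml"))
  gt <- select(study$ground_truth, -dplyr::any_of(c("formed_idx",
                                                    "resorbed_idx")))
  write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  for (t in seq_along(study$true_transforms))
    write_transform(study$true_transforms[[t]],
                    file.path(out_dir, sprintf("true_transform_%s.txt",
                                               study$labels[t])))
  invisible(study)
}

#' Analyze a longitudinal study
#'
#' Runs the full per-interval pipeline over adjacent session pairs: stack
#' assembly, ladder registration of the later onto the earlier session,
#' masking, filtering and remodeling quantification. Intervals touching a
#' casted session are analyzed but flagged (`casted = TRUE`), to be excluded
#' from downstream statistics by default. Failed (unregistered) stacks are
#' reported and the run continues on the remaining data.
#'
#' @param study A study bundle from [simulate_study()] /
#'   [make_longitudinal_study()], or a directory containing `manifest.yaml`.
#' @param out_dir Optional results directory for tidy CSVs.
#' @param method "multidensity" or "thresholded_diff".
#' @param schedule [threshold_schedule()].
#' @param filter [filter_params()].
#' @param register Set FALSE to skip registration (sessions already aligned).
#' @param fracture_spec Passed to [fracture_partition()].
#' @param ... Passed to [run_interval()].
#' @return List of tidy tibbles: `remodeling`, `quality`, `profiles`,
#'   `registration` (recovered transforms per interval).
#' @export
analyze_study <- function(study, out_dir = NULL,
                          method = c("multidensity", "thresholded_diff"),
                          schedule = threshold_schedule(),
                          filter = filter_params(), register = TRUE,
                          fracture_spec = NULL, ...) {
  method <- match.arg(method)
  if (is.character(study)) study <- load_study_dir(study)
  labels <- study$labels
  casted <- study$manifest$sessions$casted
  n <- length(study$sessions)
  remodeling <- list(); quality <- list(); profiles <- list(); regs <- list()
  for (t in seq_len(n - 1)) {
    message(sprintf("analyze: interval %s (-> %s)%s", labels[t],
                    labels[t + 1],
                    if (casted[t] || casted[t + 1]) " [casted]" else ""))
    earlier <- assemble_stacks(study$sessions[[t]])
    if (register) {
      lad <- ladder_register_stacks(study$sessions[[t]],
                                    study$sessions[[t + 1]])
      if (!all(lad$registered))
        warn(sprintf("interval %s: %d stack(s) could not be registered",
                     labels[t], sum(!lad$registered)))
      later <- lad$moving
      regs[[t]] <- tibble(interval = labels[t],
                          stack = seq_along(lad$transforms),
                          registered = lad$registered,
                          transform = lad$transforms)
    } else {
      later <- assemble_stacks(study$sessions[[t + 1]])
      later <- conform_grid(later, earlier)
    }
    res <- run_interval(earlier, later, interval = labels[t],
                        fracture_spec = fracture_spec, schedule = schedule,
                        filter = filter, method = method, ...)
    flag <- casted[t] || casted[t + 1]
    remodeling[[t]] <- mutate(res$remodeling, casted = flag)
    quality[[t]] <- mutate(res$quality, interval = labels[t], casted = flag,
                           .before = 1)
    profiles[[t]] <- mutate(res$profiles, interval = labels[t], .before = 1)
  }
  out <- list(remodeling = bind_rows(remodeling),
              quality = bind_rows(quality),
              profiles = bind_rows(profiles),
              registration = if (length(regs)) bind_rows(regs) else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_hash <- rlang::hash(list(method = method, schedule = schedule,
                                 filter = filter))
    stamp <- function(df) mutate(df, config_hash = cfg_hash)
    write.csv(stamp(out$remodeling), file.path(out_dir, "remodeling.csv"),
              row.names = FALSE)
    write.csv(stamp(out$quality), file.path(out_dir, "quality.csv"),
              row.names = FALSE)
    write.csv(stamp(out$profiles), file.path(out_dir, "profiles.csv"),
              row.names = FALSE)
  }
  out
}

# pad/crop a later assembled volume onto the earlier grid (no registration)
conform_grid <- function(vol, target) {
  if (identical(dim(vol$data), dim(target$data)) &&
      vol$offset_slices == target$offset_slices) return(vol)
  d <- dim(target$data)
  data <- array(0, d); valid <- array(FALSE, d)
  src_rows <- seq_len(dim(vol$data)[1]) + vol$offset_slices
  tgt_rows <- seq_len(d[1]) + target$offset_slices
  common <- intersect(src_rows, tgt_rows)
  if (length(common)) {
    data[common - target$offset_slices, , ] <-
      vol$data[common - vol$offset_slices, , ]
    valid[common - target$offset_slices, , ] <-
      vol$valid[common - vol$offset_slices, , ]
  }
  density_volume(data, vol$voxel_size_mm, target$offset_slices,
                 valid = valid, meta = vol$meta)
}

load_study_dir <- function(dir) {
  man <- load_manifest(file.path(dir, "manifest.yaml"))
  labels <- man$sessions$session
  sessions <- lapply(labels, function(ses) {
    st <- filter(man$stacks, .data$session == ses)
    lapply(seq_len(nrow(st)), function(i) {
      v <- read_volume(file.path(dir, st$file[i]))
      v$offset_slices <- st$offset_slices[i]
      v$meta <- list(session = ses)
      v
    })
  })
  list(sessions = sessions, labels = labels, manifest = man)
}

#' Summarize remodeling results
#'
#' Median (IQR) formation and resorption per interval, bone type, partition
#' and threshold, plus a formation-minus-resorption column. With several
#' patients, each cell's formation/resorption difference is tested with the
#' paired form of [partially_paired_test()] and flagged after Holm
#' correction across cells; casted intervals are excluded from testing.
#'
#' @param remodeling A `remodeling_result` tibble (may carry a `patient`
#'   column).
#' @param alpha Familywise error rate for the Holm flags.
#' @return Summary tibble.
#' @export
report_study <- function(remodeling, alpha = 0.05) {
  if (nrow(remodeling) == 0) abort("empty results")
  if (!"patient" %in% names(remodeling))
    remodeling$patient <- "P1"
  if (!"casted" %in% names(remodeling)) remodeling$casted <- FALSE
  iqr_fmt <- function(v) sprintf("%.3f (%.3f)", median(v, na.rm = TRUE),
                                 stats::IQR(v, na.rm = TRUE))
  summ <- remodeling |>
    group_by(.data$interval, .data$bone_type, .data$partition,
             .data$threshold) |>
    summarise(
      n_patients = dplyr::n_distinct(.data$patient),
      formation_median = median(.data$formation_fraction, na.rm = TRUE),
      formation_iqr = stats::IQR(.data$formation_fraction, na.rm = TRUE),
      resorption_median = median(.data$resorption_fraction, na.rm = TRUE),
      resorption_iqr = stats::IQR(.data$resorption_fraction, na.rm = TRUE),
      casted = any(.data$casted),
      .groups = "drop") |>
    mutate(formation_minus_resorption =
             .data$formation_median - .data$resorption_median)
  multi <- summ$n_patients[1] > 1
  if (multi) {
    cells <- summ |> filter(!.data$casted)
    pv <- purrr::map_dbl(seq_len(nrow(cells)), function(i) {
      sub <- remodeling |>
        filter(.data$interval == cells$interval[i],
               .data$bone_type == cells$bone_type[i],
               .data$partition == cells$partition[i],
               .data$threshold == cells$threshold[i],
               !.data$casted,
               is.finite(.data$formation_fraction),
               is.finite(.data$resorption_fraction))
      if (nrow(sub) < 3) return(NA_real_)
      partially_paired_test(paired_x = abs(sub$formation_fraction),
                            paired_y = abs(sub$resorption_fraction),
                            var_equal = FALSE)$p.value
    })
    okp <- is.finite(pv)
    flags <- rep(NA, nrow(cells))
    padj <- rep(NA_real_, nrow(cells))
    if (any(okp)) {
      hb <- holm_bonferroni(pv[okp], alpha)
      flags[okp] <- hb$reject
      padj[okp] <- hb$p.adjusted
    }
    cells$p_value <- pv; cells$p_adjusted <- padj; cells$significant <- flags
    summ <- left_join(summ, select(cells, dplyr::all_of(c(
      "interval", "bone_type", "partition", "threshold",
      "p_value", "p_adjusted", "significant"))),
      by = c("interval", "bone_type", "partition", "threshold"))
  }
  summ
}
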