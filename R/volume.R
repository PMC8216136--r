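# Calibrated density volumes.
#
# Layout convention (fixed across the package): a volume is a 3D array with
# dim = c(slices, rows, columns); axis 1 is the axial (slice) axis along which
# stacks are concatenated. Voxel indices are 0-based in physical formulas and
# the physical position of voxel (i, j, k) is
#   origin_mm + voxel_size_mm * (i, j, k)          (voxel-center convention)
# where origin_mm = c(axial_offset_slices * voxel_size_mm, 0, 0).

#' Create a calibrated density volume
#'
#' Wraps a 3D array of mineral densities (mg HA/cm^3) together with its voxel
#' size, its axial position relative to the study reference line, a validity
#' mask and per-session metadata. Axis 1 is the axial (slice) axis.
#'
#' @param data 3D numeric array, densities in mg HA/cm^3.
#' @param voxel_size_mm Isotropic voxel edge length in mm (default 0.0607,
#'   the second-generation HRpQCT voxel).
#' @param offset_slices Integer axial offset of the first slice relative to
#'   the study reference line, in slices.
#' @param valid Logical array of the same shape marking voxels that carry
#'   measured data (e.g. voxels that stayed inside the source grid during
#'   resampling). Default: all valid.
#' @param meta Named list of session metadata. Recognised fields: `session`
#'   (label), `arm` ("fractured"/"contralateral"), `casted` (logical), `vgs`
#'   (visual grading score, integer 1-5).
#' @return A `density_volume` object.
#' @export
density_volume <- function(data, voxel_size_mm = 0.0607, offset_slices = 0L,
                           valid = NULL, meta = list()) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    abort("`voxel_size_mm` must be > 0")
  if (is.null(valid)) {
    valid <- array(TRUE, dim = dim(data))
  } else {
    if (!identical(dim(valid), dim(data)))
      abort("`valid` must have the same shape as `data`")
    valid <- array(as.logical(valid), dim = dim(data))
  }
  if (!is.null(meta$vgs) && !meta$vgs %in% 1:5)
    abort("VGS grade must be in 1..5")
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm,
         offset_slices = as.integer(offset_slices), valid = valid,
         meta = meta),
    class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_volume> %d x %d x %d voxels @ %.4f mm, offset %d slices\n",
              d[1], d[2], d[3], x$voxel_size_mm, x$offset_slices))
  cat(sprintf("  density range [%.1f, %.1f] mg HA/cm^3, %.1f%% valid\n",
              min(x$data), max(x$data), 100 * mean(x$valid)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$data)

# physical origin (mm) of voxel (0,0,0)
vol_origin <- function(v) c(v$offset_slices * v$voxel_size_mm, 0, 0)

#' Linear density calibration
#'
#' Linear map from raw scanner grayscale to mg HA/cm^3:
#' density = slope * raw + intercept.
#'
#' @param slope,intercept Calibration coefficients; `slope` must be > 0.
#' @return A `calibration` object.
#' @export
calibration <- function(slope = 1, intercept = 0) {
  if (slope <= 0) abort("calibration slope must be > 0")
  structure(list(slope = slope, intercept = intercept), class = "calibration")
}

#' Apply or invert a density calibration
#'
#' @param x Numeric array or `density_volume`.
#' @param cal A [calibration()].
#' @param inverse Map densities back to raw values.
#' @return Same shape as `x`.
#' @export
apply_calibration <- function(x, cal, inverse = FALSE) {
  stopifnot(inherits(cal, "calibration"))
  f <- if (inverse) function(d) (d - cal$intercept) / cal$slope
       else function(d) cal$slope * d + cal$intercept
  if (inherits(x, "density_volume")) { x$data <- f(x$data); x } else f(x)
}

# ---- file formats -----------------------------------------------------------

vol_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.mha$", p)) "mha"
  else if (grepl("\\.nii(\\.gz)?$", p)) "nifti"
  else if (grepl("\\.tiff?$", p)) "tiff"
  else abort(paste0("unrecognised volume format: ", path))
}

#' Read a density or label volume
#'
#' Supports MetaImage (`.mha`, uncompressed), NIfTI (`.nii`, `.nii.gz`) and
#' multi-page TIFF stacks (32-bit float samples holding density / 4096). Anisotropic voxels are rejected: the pipeline
#' assumes isotropic voxels throughout. A companion validity file
#' `<stem>_valid.<ext>` is picked up automatically when present.
#'
#' @param path File to read.
#' @param cal Optional [calibration()] applied to raw values on read.
#' @param voxel_size_mm Voxel size for formats that do not store it (TIFF).
#' @param offset_slices Axial offset for formats that do not store it.
#' @return A [density_volume()].
#' @export
read_volume <- function(path, cal = NULL, voxel_size_mm = 0.0607,
                        offset_slices = 0L) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  fmt <- vol_format(path)
  if (fmt == "mha") {
    r <- read_mha(path)
    data <- r$data; vox <- r$voxel; off <- r$offset
  } else if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3]
    if (max(pd) - min(pd) > 1e-6 * max(pd))
      abort(sprintf("anisotropic voxels (%s mm): pipeline assumes isotropic voxels",
                    paste(signif(pd, 4), collapse = " x ")))
    data <- array(as.numeric(img), dim = dim(img)[1:3])
    vox <- pd[1]
    off <- attr(img, "remodelr_offset") %||% 0L
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("the 'tiff' package is required to read TIFF stacks")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    data <- aperm(simplify2array(pages), c(3, 1, 2)) * tiff_full_scale
    vox <- voxel_size_mm
    off <- offset_slices
  }
  valid_path <- companion_valid_path(path)
  valid <- NULL
  if (file.exists(valid_path)) {
    vv <- read_volume(valid_path, voxel_size_mm = vox)
    valid <- vv$data > 0.5
  }
  if (!is.null(cal)) data <- apply_calibration(data, cal)
  density_volume(data, voxel_size_mm = vox, offset_slices = off, valid = valid)
}

companion_valid_path <- function(path) {
  ext <- sub("^.*?(\\.(mha|nii(\\.gz)?|tiff?))$", "\\1", path,
             ignore.case = TRUE)
  paste0(substr(path, 1, nchar(path) - nchar(ext)), "_valid", ext)
}

#' Write a density or label volume
#'
#' Format is inferred from the extension (`.mha`, `.nii`, `.nii.gz`, `.tif`).
#' If the volume carries invalid voxels, a companion `<stem>_valid` volume is
#' written next to it so validity never has to be encoded as a sentinel
#' density.
#'
#' @param volume A [density_volume()] (or plain 3D array for masks).
#' @param path Output path.
#' @param write_valid Write companion validity file when needed.
#' @export
write_volume <- function(volume, path, write_valid = TRUE) {
  if (!inherits(volume, "density_volume"))
    volume <- density_volume(volume)
  fmt <- vol_format(path)
  if (fmt == "mha") {
    write_mha(volume$data, path, volume$voxel_size_mm, volume$offset_slices)
  } else if (fmt == "nifti") {
    img <- RNifti::asNifti(volume$data)
    RNifti::pixdim(img) <- rep(volume$voxel_size_mm, 3)
    RNifti::writeNifti(img, path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("the 'tiff' package is required to write TIFF stacks")
    d <- volume$data / tiff_full_scale
    if (min(d) < 0 || max(d) > 1)
      abort("TIFF output supports densities in [0, 4096] mg HA/cm^3")
    pages <- lapply(seq_len(dim(d)[1]), function(i) d[i, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  if (write_valid && !all(volume$valid)) {
    vp <- companion_valid_path(path)
    write_volume(density_volume(array(as.numeric(volume$valid),
                                      dim = dim(volume$data)),
                                volume$voxel_size_mm, volume$offset_slices),
                 vp, write_valid = FALSE)
  }
  invisible(path)
}

# Minimal MetaImage (uncompressed MET_DOUBLE/MET_FLOAT/...) support; no R
# package in the stack reads MetaImage. Voxel size kept to 6 significant
# digits; the axial offset rides in the Offset header field.
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) abort("truncated MetaImage header")
    kv <- strsplit(line, "\\s*=\\s*")[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  if (max(spacing) - min(spacing) > 1e-6 * max(spacing))
    abort("anisotropic voxels: pipeline assumes isotropic voxels")
  offset <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr$ElementType
  n <- prod(dims)
  raw_vals <- switch(type,
    MET_DOUBLE = readBin(con, "double", n = n, size = 8),
    MET_FLOAT  = readBin(con, "double", n = n, size = 4),
    MET_SHORT  = readBin(con, "integer", n = n, size = 2, signed = TRUE),
    MET_USHORT = readBin(con, "integer", n = n, size = 2, signed = FALSE),
    MET_UCHAR  = as.integer(readBin(con, "raw", n = n)),
    abort(paste0("unsupported MetaImage element type: ", type)))
  # MetaImage stores x fastest; our axis 1 (axial) is written as z there, so
  # we write/read with our axis order reversed in DimSize.
  data <- array(as.numeric(raw_vals), dim = dims)
  data <- aperm(data, c(3, 2, 1))
  list(data = data, voxel = spacing[1],
       offset = as.integer(round(offset[3] / spacing[1])))
}

write_mha <- function(data, path, voxel_mm, offset_slices = 0L) {
  dims <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  vox <- signif(voxel_mm, 6)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", dims[3], dims[2], dims[1]),
           sprintf("ElementSpacing = %.10g %.10g %.10g", vox, vox, vox),
           sprintf("Offset = 0 0 %.10g", offset_slices * vox),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.numeric(aperm(data, c(3, 2, 1))), con, size = 8)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TIFF stacks carry density / 4096 as 32-bit float samples in [0, 1]
tiff_full_scale <- 4096

# ---- study manifests --------------------------------------------------------

#' Load a study manifest
#'
#' A manifest (YAML) lists imaging sessions in time order, each with its
#' stacks (file, axial offset in slices, length), casted flag, arm and VGS
#' grade, plus an optional fracture region given as an axial slice interval.
#' Sessions are returned ordered by time index and stacks by axial offset;
#' overlapping stacks within a session or missing stack files are errors.
#'
#' @param path Manifest YAML file.
#' @return A list with `sessions` (tibble), `stacks` (tibble) and
#'   `fracture_slices` (length-2 integer vector or NULL).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  m <- yaml::read_yaml(path)
  root <- dirname(path)
  sessions <- purrr::map_dfr(m$sessions, function(s) {
    tibble(session = s$session, time_index = s$time_index,
           arm = s$arm %||% "fractured",
           casted = isTRUE(s$casted), vgs = s$vgs %||% NA_integer_)
  })
  sessions <- arrange(sessions, .data$time_index)
  stacks <- purrr::map_dfr(m$sessions, function(s) {
    purrr::map_dfr(s$stacks, function(st) {
      tibble(session = s$session, file = st$file,
             offset_slices = as.integer(st$offset_slices),
             n_slices = as.integer(st$n_slices))
    })
  })
  stacks <- arrange(stacks, match(.data$session, sessions$session),
                    .data$offset_slices)
  for (ses in unique(stacks$session)) {
    st <- filter(stacks, .data$session == ses)
    if (nrow(st) > 1) {
      ends <- st$offset_slices + st$n_slices
      if (any(st$offset_slices[-1] < ends[-nrow(st)]))
        abort(paste0("overlapping stacks in session ", ses))
    }
    miss <- st$file[!file.exists(file.path(root, st$file))]
    if (length(miss))
      abort(sprintf("missing stack file(s) in session %s: %s", ses,
                    paste(miss, collapse = ", ")))
  }
  fr <- NULL
  if (!is.null(m$fracture_slices)) fr <- as.integer(unlist(m$fracture_slices))
  list(sessions = sessions, stacks = stacks, fracture_slices = fr,
       voxel_size_mm = m$voxel_size_mm %||% 0.0607, root = root)
}

write_manifest <- function(bundle, path) {
  sess <- lapply(seq_len(nrow(bundle$sessions)), function(i) {
    s <- bundle$sessions[i, ]
    st <- dplyr::filter(bundle$stacks, .data$session == s$session)
    list(session = s$session, time_index = s$time_index, arm = s$arm,
         casted = s$casted, vgs = s$vgs,
         stacks = lapply(seq_len(nrow(st)), function(j)
           list(file = st$file[j], offset_slices = st$offset_slices[j],
                n_slices = st$n_slices[j])))
  })
  out <- list(voxel_size_mm = bundle$voxel_size_mm, sessions = sess)
  if (!is.null(bundle$fracture_slices))
    out$fracture_slices <- as.integer(bundle$fracture_slices)
  yaml::write_yaml(out, path)
  invisible(path)
}
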