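# 6-parameter rigid transforms mapping moving -> fixed physical coordinates:
#   T(x) = R (x - c) + c + t
# with R = R1(a1) R2(a2) R3(a3) (right-handed rotations about the array axes,
# axis 1 = axial), angles in degrees, translations and center in mm.

#' Create a rigid transform
#'
#' @param rotation_deg Euler angles (degrees) about array axes 1 (axial), 2, 3;
#'   applied as R = R1 R2 R3.
#' @param translation_mm Translation vector (mm).
#' @param center_mm Rotation center (mm).
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm),
                 center_mm = as.numeric(center_mm)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s | trans (mm): %s | center (mm): %s\n",
              paste(signif(x$rotation_deg, 5), collapse = ", "),
              paste(signif(x$translation_mm, 5), collapse = ", "),
              paste(signif(x$center_mm, 5), collapse = ", ")))
  invisible(x)
}

rot_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  c1 <- cos(a[1]); s1 <- sin(a[1])
  c2 <- cos(a[2]); s2 <- sin(a[2])
  c3 <- cos(a[3]); s3 <- sin(a[3])
  R1 <- matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
  R2 <- matrix(c(c2, 0, -s2, 0, 1, 0, s2, 0, c2), 3, 3)
  R3 <- matrix(c(c3, s3, 0, -s3, c3, 0, 0, 0, 1), 3, 3)
  R1 %*% R2 %*% R3
}

# Euler angles (deg) from R = R1(a) R2(b) R3(c); valid away from b = +/-90 deg.
euler_from_matrix <- function(R) {
  b <- asin(max(-1, min(1, R[1, 3])))
  a <- atan2(-R[2, 3], R[3, 3])
  cc <- atan2(-R[1, 2], R[1, 1])
  c(a, b, cc) * 180 / pi
}

# affine form T(x) = M x + d
rt_affine <- function(tr) {
  M <- rot_matrix(tr$rotation_deg)
  d <- tr$center_mm + tr$translation_mm - as.numeric(M %*% tr$center_mm)
  list(M = M, d = d)
}

affine_to_rt <- function(M, d, center_mm = c(0, 0, 0)) {
  rigid_transform(rotation_deg = euler_from_matrix(M),
                  translation_mm = d - center_mm + as.numeric(M %*% center_mm),
                  center_mm = center_mm)
}

#' Apply a rigid transform to points
#'
#' @param tr A [rigid_transform()].
#' @param pts n x 3 matrix of physical points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(tr, pts) {
  pts <- rbind(pts)
  af <- rt_affine(tr)
  t(af$M %*% t(pts) + af$d)
}

#' Invert a rigid transform
#'
#' Composition with the inverse is the identity to machine precision.
#'
#' @param tr A [rigid_transform()].
#' @return The inverse `rigid_transform`, reported about the same center.
#' @export
invert_transform <- function(tr) {
  af <- rt_affine(tr)
  Mi <- t(af$M)
  di <- -as.numeric(Mi %*% af$d)
  affine_to_rt(Mi, di, tr$center_mm)
}

#' Compose rigid transforms
#'
#' `compose_transforms(t2, t1)` applies `t1` first, then `t2`.
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return The composed `rigid_transform` (centered at `t2`'s center).
#' @export
compose_transforms <- function(t2, t1) {
  a2 <- rt_affine(t2); a1 <- rt_affine(t1)
  affine_to_rt(a2$M %*% a1$M, as.numeric(a2$M %*% a1$d) + a2$d, t2$center_mm)
}

#' Read/write plain-text transform files
#'
#' Transforms are serialized as a small key-value text file holding the three
#' Euler angles (degrees), the translation (mm) and the explicit rotation
#' center (mm).
#'
#' @param tr A [rigid_transform()].
#' @param path File path.
#' @return `read_transform` returns a `rigid_transform`.
#' @export
write_transform <- function(tr, path) {
  writeLines(c(
    sprintf("rotation_deg: %.17g %.17g %.17g", tr$rotation_deg[1],
            tr$rotation_deg[2], tr$rotation_deg[3]),
    sprintf("translation_mm: %.17g %.17g %.17g", tr$translation_mm[1],
            tr$translation_mm[2], tr$translation_mm[3]),
    sprintf("center_mm: %.17g %.17g %.17g", tr$center_mm[1],
            tr$center_mm[2], tr$center_mm[3])), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  ln <- readLines(path)
  get <- function(key) {
    l <- grep(paste0("^", key, ":"), ln, value = TRUE)
    as.numeric(strsplit(sub(paste0(key, ":\\s*"), "", l), "\\s+")[[1]])
  }
  rigid_transform(get("rotation_deg"), get("translation_mm"), get("center_mm"))
}
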