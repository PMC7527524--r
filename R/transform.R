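# Rigid (6-DOF) transforms in the patient frame and volume resampling.
#
# Patient frame used throughout the package: +x toward patient left,
# +y anterior, +z superior ("LAS"). A voxel with zero-based index i along an
# axis sits at coordinate i * spacing on that axis, so R arrays (1-based)
# place voxel [i, j, k] at ((i, j, k) - 1) * spacing millimetres.

#' Construct a rigid transform
#'
#' A 6-DOF rigid-body transform: rotation by Euler angles about a fixed
#' centre followed by a translation, acting on points in millimetres in the
#' patient frame. Internally the transform is stored as `p' = R p + offset`,
#' so composition and inversion are exact matrix operations.
#'
#' @param rotation numeric length 3, rotation angles in degrees about the
#'   x, y and z axes; the rotation matrix is `Rz %*% Ry %*% Rx`.
#' @param translation numeric length 3, translation in mm.
#' @param center numeric length 3, centre of rotation in mm (typically the
#'   volume centre).
#' @return an object of class `rigid_transform`.
#' @examples
#' tf <- rigid_transform(rotation = c(0, 0, 90), translation = c(1, 0, 0))
#' rt_apply(tf, c(1, 0, 0))  # ~ (1, 1, 0)
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            length(center) == 3, all(is.finite(c(rotation, translation, center))))
  R <- euler_matrix(rotation)
  offset <- as.numeric(center + translation - R %*% center)
  rt_from_matrix(R, offset, center = center)
}

euler_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

rt_from_matrix <- function(R, offset, center = c(0, 0, 0)) {
  if (abs(det(R) - 1) > 1e-8 || max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation matrix is not a proper rotation (orthonormal, det = +1)")
  structure(list(R = R, offset = as.numeric(offset), center = as.numeric(center)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf a `rigid_transform`.
#' @param pts numeric length 3 or an n x 3 matrix of points (mm).
#' @return points of the same shape as the input.
#' @export
rt_apply <- function(tf, pts) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.null(dim(pts))) {
    stopifnot(length(pts) == 3)
    return(as.numeric(tf$R %*% pts + tf$offset))
  }
  stopifnot(ncol(pts) == 3)
  sweep(pts %*% t(tf$R), 2, tf$offset, `+`)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
rt_invert <- function(tf) {
  Rt <- t(tf$R)
  rt_from_matrix(Rt, -as.numeric(Rt %*% tf$offset), center = tf$center)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform applying `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return the composed `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rt_from_matrix(a$R %*% b$R, as.numeric(a$R %*% b$offset + a$offset),
                 center = a$center)
}

rt_identity <- function(center = c(0, 0, 0)) rigid_transform(center = center)

#' Extract Euler angles and translation of a rigid transform
#'
#' Decomposes the transform as a rotation about `center` followed by a
#' translation, the parameterisation used by [rigid_transform()].
#'
#' @param tf a `rigid_transform`.
#' @param center centre of rotation (mm); defaults to the one stored in `tf`.
#' @return list with `rotation` (deg, x/y/z) and `translation` (mm).
#' @export
rt_parameters <- function(tf, center = tf$center) {
  R <- tf$R
  # inverse of Rz(z) Ry(y) Rx(x); |y| < 90 deg assumed (small-angle use)
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  rot <- c(rx, ry, rz) * 180 / pi
  trans <- as.numeric(tf$offset - center + R %*% center)
  list(rotation = rot, translation = trans)
}

#' @export
print.rigid_transform <- function(x, ...) {
  p <- rt_parameters(x)
  cat("rigid_transform: rotation (deg x,y,z) =",
      paste(signif(p$rotation, 4), collapse = ", "),
      "| translation (mm) =",
      paste(signif(p$translation, 4), collapse = ", "), "\n")
  invisible(x)
}

# Trilinear / nearest sampling of a 3D array at continuous 1-based indices.
# Points outside the grid return `background`. `ci` is an n x 3 matrix.
sample_array <- function(arr, ci, interpolation = "linear", background = 0) {
  d <- dim(arr)
  out <- rep(background, nrow(ci))
  if (interpolation == "nearest") {
    i <- round(ci[, 1]); j <- round(ci[, 2]); k <- round(ci[, 3])
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    idx <- i[ok] + (j[ok] - 1) * d[1] + (k[ok] - 1) * d[1] * d[2]
    out[ok] <- arr[idx]
    return(out)
  }
  ok <- ci[, 1] >= 1 & ci[, 1] <= d[1] &
        ci[, 2] >= 1 & ci[, 2] <= d[2] &
        ci[, 3] >= 1 & ci[, 3] <= d[3]
  if (!any(ok)) return(out)
  x <- ci[ok, 1]; y <- ci[ok, 2]; z <- ci[ok, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  nx <- d[1]; nxy <- d[1] * d[2]
  at <- function(i, j, k) arr[i + (j - 1) * nx + (k - 1) * nxy]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
       at(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
       at(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
       at(x1, y1, z0) * fx       * fy       * (1 - fz) +
       at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
       at(x1, y0, z1) * fx       * (1 - fy) * fz +
       at(x0, y1, z1) * (1 - fx) * fy       * fz +
       at(x1, y1, z1) * fx       * fy       * fz
  out[ok] <- v
  out
}

# millimetre coordinates of all voxel centres, as three vectors
grid_axes <- function(dim, spacing) {
  list(x = (seq_len(dim[1]) - 1) * spacing[1],
       y = (seq_len(dim[2]) - 1) * spacing[2],
       z = (seq_len(dim[3]) - 1) * spacing[3])
}

# n x 3 matrix of voxel-centre coordinates for the given (1-based) indices
voxel_mm <- function(idx, spacing) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep(idx - 1, 2, spacing, `*`)
}

volume_center_mm <- function(dim, spacing) (dim - 1) * spacing / 2

#' Resample a volume under a rigid transform
#'
#' Moves the content of `vol` by `tf` and resamples it on the same voxel
#' grid: the output at voxel position `p` is the input sampled at
#' `tf^-1(p)`. Voxels mapping outside the field of view are set to
#' `background`.
#'
#' @param vol an [ot_volume()].
#' @param tf a [rigid_transform()].
#' @param interpolation `"linear"` (default, for intensities) or
#'   `"nearest"` (for masks/labels).
#' @param background value for out-of-field voxels.
#' @return an `ot_volume` on the same grid.
#' @export
apply_rigid <- function(vol, tf, interpolation = c("linear", "nearest"),
                        background = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(vol, "ot_volume"), inherits(tf, "rigid_transform"))
  d <- dim(vol$data)
  ax <- grid_axes(d, vol$spacing)
  pts <- cbind(rep(ax$x, times = d[2] * d[3]),
               rep(rep(ax$y, each = d[1]), times = d[3]),
               rep(ax$z, each = d[1] * d[2]))
  q <- rt_apply(rt_invert(tf), pts)
  ci <- sweep(q, 2, vol$spacing, `/`) + 1
  v <- sample_array(vol$data, ci, interpolation, background)
  out <- vol
  out$data <- array(v, dim = d)
  out
}
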