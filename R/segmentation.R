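# Globe segmentation by seeded region growing, centroid and volume
# measures, and a pole-vector rotation estimate.
#
# The globe proxy is the bright vitreous interior (what a tolerance-based
# wand selection traces on T2 images); the dark scleral shell is included
# only when `shell_mm > 0`. The centroid is the unweighted arithmetic mean
# of member voxel centres, converted to mm per-axis because the voxel
# spacing is anisotropic.

#' Seed specification for region growing
#'
#' @param seed either `"auto"` (locate the brightest smoothed voxel on the
#'   requested side) or an integer 1-based voxel index `c(i, j, k)`.
#' @param tolerance inclusion tolerance as a fraction of the seed
#'   intensity, in `(0, 1)`.
#' @return list of class `seed_spec`.
#' @export
seed_spec <- function(seed = "auto", tolerance = 0.25) {
  if (!(identical(seed, "auto") || (is.numeric(seed) && length(seed) == 3)))
    stop("seed must be \"auto\" or a length-3 voxel index")
  if (tolerance <= 0 || tolerance >= 1) stop("tolerance must be in (0, 1)")
  structure(list(seed = seed, tolerance = tolerance), class = "seed_spec")
}

# brightest 3x3x3-smoothed voxel in the half-grid of the requested side;
# patient-left is +x, so the left eye lives at high x index
auto_seed <- function(vol, side) {
  d <- dim(vol$data)
  sm <- box3_mean(vol$data)
  half <- array(FALSE, dim = d)
  mid <- floor(d[1] / 2)
  if (side == "left") half[(mid + 1):d[1], , ] <- TRUE else half[1:mid, , ] <- TRUE
  sm[!half] <- -Inf
  arrayInd(which.max(sm), d)[1, ]
}

#' Segment one globe by seeded region growing
#'
#' Grows a 6-connected region from the seed, including voxels whose
#' intensity lies within `tolerance * seed intensity` of the seed, then
#' applies a one-voxel morphological closing, fills interior cavities
#' (lens), and keeps the largest connected component. The result is
#' invariant to rescaling the intensities.
#'
#' @param vol an [ot_volume()].
#' @param seed a [seed_spec()].
#' @param side `"left"` or `"right"` (patient side); required for
#'   `seed = "auto"` and recorded on the mask.
#' @param shell_mm optional dilation (mm) to include the scleral shell;
#'   0 (default) keeps the vitreous-interior proxy.
#' @return object of class `globe_mask`: list with logical `voxels`,
#'   `side`, `gaze`, `spacing`, `seed`.
#' @export
segment_globe <- function(vol, seed = seed_spec(), side = c("left", "right"),
                          shell_mm = 0) {
  stopifnot(inherits(vol, "ot_volume"), inherits(seed, "seed_spec"))
  side <- match.arg(side)
  d <- dim(vol$data)
  idx <- if (identical(seed$seed, "auto")) auto_seed(vol, side) else
    as.integer(round(seed$seed))
  if (any(idx < 1) || any(idx > d)) stop("seed voxel outside the grid")
  iseed <- vol$data[idx[1], idx[2], idx[3]]
  scale <- stats::quantile(abs(vol$data), 0.999, names = FALSE)
  if (abs(iseed) <= 0.05 * scale)
    stop("bad seed: seed intensity is not above background")
  within <- abs(vol$data - iseed) <= seed$tolerance * abs(iseed)
  seeds <- array(FALSE, dim = d); seeds[idx[1], idx[2], idx[3]] <- TRUE
  grown <- flood_fill(within, seeds)
  if (touches_boundary(grown))
    stop("segmentation leak: grown region touches the grid boundary")
  closed <- close6(grown)
  filled <- fill_holes(closed)
  # a globe is a compact bright blob with at most a small lens cavity; a
  # seed in surrounding tissue grows a shell around the globe instead
  cavity <- (sum(filled) - sum(closed)) / sum(filled)
  if (cavity > 0.2)
    stop(sprintf(
      "bad seed: grown region surrounds a cavity (%.0f%% of its filled volume)",
      100 * cavity))
  mask <- largest_component(filled)
  if (shell_mm > 0) mask <- dilate_mm(mask, shell_mm, vol$spacing)
  vol_ml <- sum(mask) * prod(vol$spacing) / 1000
  if (vol_ml < 1)
    stop(sprintf("bad seed: segmented region is %.2f ml (< 1 ml)", vol_ml))
  structure(list(voxels = mask, side = side, gaze = vol$gaze,
                 spacing = vol$spacing, seed = idx),
            class = "globe_mask")
}

mask_array <- function(mask) if (inherits(mask, "globe_mask")) mask$voxels else mask

mask_spacing <- function(mask, spacing = NULL) {
  if (!is.null(spacing)) return(spacing)
  if (inherits(mask, "globe_mask")) return(mask$spacing)
  sp <- attr(mask, "spacing")
  if (is.null(sp)) stop("spacing not supplied and not attached to the mask")
  sp
}

#' Centroid of a binary mask in millimetres
#'
#' The unweighted arithmetic mean position of all member voxel centres,
#' each axis scaled by its own spacing (the pixel-to-mm conversion). Voxel
#' `[i, j, k]` (1-based) contributes position `((i,j,k) - 1) * spacing`.
#'
#' @param mask a `globe_mask` or logical array.
#' @param spacing voxel spacing (mm); taken from the mask if absent.
#' @return object of class `centroid_mm`: numeric `c(x, y, z)` in mm with
#'   `side` and `gaze` attributes when known.
#' @export
centroid_mm <- function(mask, spacing = NULL) {
  arr <- mask_array(mask)
  sp <- mask_spacing(mask, spacing)
  if (!any(arr)) stop("empty mask has no centroid")
  idx <- which(arr, arr.ind = TRUE)
  ctr <- colMeans(voxel_mm(idx, sp))
  structure(as.numeric(ctr), names = c("x", "y", "z"),
            side = if (inherits(mask, "globe_mask")) mask$side else NULL,
            gaze = if (inherits(mask, "globe_mask")) mask$gaze else NULL,
            class = "centroid_mm")
}

#' Volume of a binary mask in millilitres
#'
#' Voxel count times voxel volume.
#' @inheritParams centroid_mm
#' @return scalar volume in ml.
#' @export
mask_volume_ml <- function(mask, spacing = NULL) {
  arr <- mask_array(mask)
  sp <- mask_spacing(mask, spacing)
  if (!any(arr)) stop("empty mask has no volume")
  sum(arr) * prod(sp) / 1000
}

#' Eyeball rotation angle from centroid-to-pole vectors
#'
#' The angle between the centroid-to-anterior-pole vectors of two gazes,
#' measured in the gaze plane (`axial` for horizontal gaze, `sagittal` for
#' vertical). Because both vectors are differences within one gaze, a
#' common translation of the globe cancels and the estimate isolates
#' rotation.
#'
#' @param centroid1,pole1 centroid and pole landmark (mm) in the primary
#'   gaze; the phantom's lens centroid serves as the pole.
#' @param centroid2,pole2 the same for the secondary gaze, in the same
#'   registered frame.
#' @param plane `"axial"` (x-y) or `"sagittal"` (y-z).
#' @return rotation angle in degrees, `>= 0`.
#' @export
estimate_rotation_deg <- function(centroid1, pole1, centroid2, pole2,
                                  plane = c("axial", "sagittal")) {
  plane <- match.arg(plane)
  dims <- if (plane == "axial") c(1, 2) else c(2, 3)
  v1 <- (as.numeric(pole1) - as.numeric(centroid1))[dims]
  v2 <- (as.numeric(pole2) - as.numeric(centroid2))[dims]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("pole coincides with centroid")
  abs(atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2))) * 180 / pi
}
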