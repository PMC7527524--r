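# Distance and direction of centroid movement between central and
# secondary gaze, with plane projection, per-eye mirroring and the two
# reporting angle conventions.
#
# Horizontal gaze is analysed in the axial (x-y) plane with medial = 0 deg
# and anterior = 90 deg; because adduction/abduction are mirror-symmetric
# about the midline, the lateral-medial component of the right eye is
# negated so both eyes share the left-eye convention. Vertical gaze is
# analysed in the sagittal (y-z) plane with anterior = 0 deg, up = 90 deg,
# down = -90 deg; no mirroring is needed. A one-argument arctangent of the
# coordinate ratio is quadrant-ambiguous, so the two-argument arctangent is
# used throughout.

#' Wrap an angle into a canonical range
#'
#' @param theta angle(s) in degrees.
#' @param range `"signed"` for `(-180, 180]` or `"positive"` for
#'   `[0, 360)`.
#' @return wrapped angle(s).
#' @examples
#' wrap_angle(228.7, "signed")   # -131.3
#' wrap_angle(-4.2, "positive")  # 355.8
#' @export
wrap_angle <- function(theta, range = c("signed", "positive")) {
  range <- match.arg(range)
  stopifnot(all(is.finite(theta)))
  s <- theta %% 360
  if (range == "positive") return(s)
  ifelse(s > 180, s - 360, s)
}

new_displacement <- function(d, theta, plane, angle_range, side, gaze,
                             out_of_plane_mm) {
  undefined <- d == 0
  structure(list(d = d,
                 theta = if (undefined) NA_real_ else wrap_angle(theta, angle_range),
                 theta_undefined = undefined, plane = plane,
                 angle_range = angle_range, side = side, gaze = gaze,
                 out_of_plane_mm = out_of_plane_mm),
            class = "displacement")
}

#' @export
print.displacement <- function(x, ...) {
  cat(sprintf("displacement (%s plane, %s eye, gaze %s): d = %.3f mm, theta = %s\n",
              x$plane, x$side, x$gaze, x$d,
              if (x$theta_undefined) "undefined (d = 0)"
              else sprintf("%.1f deg (%s)", x$theta, x$angle_range)))
  invisible(x)
}

check_pair <- function(c1, c2, side) {
  s1 <- attr(c1, "side"); s2 <- attr(c2, "side")
  for (s in list(s1, s2))
    if (!is.null(s) && s != side)
      stop("centroid side does not match the requested side")
  if (!is.null(s1) && !is.null(s2) && s1 != s2)
    stop("centroids come from different eyes")
}

#' Horizontal (axial-plane) centroid displacement
#'
#' Distance `d = sqrt(du^2 + dv^2)` and direction
#' `theta = atan2(dv, du)` where `du` is the medial component of the
#' centroid shift (the right eye's lateral-medial shift is negated so both
#' eyes read in the left-eye convention: medial 0 deg, anterior 90 deg,
#' lateral 180 deg, posterior 270 deg/-90 deg) and `dv` the anterior
#' component. The vertical (out-of-plane) shift is recorded but not
#' analysed.
#'
#' @param c1,c2 [centroid_mm()] of the same eye in central and secondary
#'   gaze, both in the registered central-gaze frame.
#' @param side `"left"` or `"right"` patient eye.
#' @param angle_range `"signed"` or `"positive"` reporting convention.
#' @param gaze gaze label for the record; defaults to `c2`'s label.
#' @return a `displacement` (fields `d`, `theta`, `theta_undefined`,
#'   `plane`, `out_of_plane_mm`).
#' @export
horizontal_displacement <- function(c1, c2, side = c("left", "right"),
                                    angle_range = c("signed", "positive"),
                                    gaze = NULL) {
  side <- match.arg(side); angle_range <- match.arg(angle_range)
  check_pair(c1, c2, side)
  delta <- as.numeric(c2) - as.numeric(c1)
  du <- if (side == "right") delta[1] else -delta[1]  # medial component
  dv <- delta[2]                                      # anterior component
  d <- sqrt(du^2 + dv^2)
  new_displacement(d, atan2(dv, du) * 180 / pi, "axial", angle_range, side,
                   gaze %||% attr(c2, "gaze") %||% "", delta[3])
}

#' Vertical (sagittal-plane) centroid displacement
#'
#' Distance over the antero-posterior and vertical shifts and direction
#' `theta = atan2(dz, dy)` (anterior 0 deg, up 90 deg, down -90 deg);
#' both eyes are treated alike since y and z are side-symmetric.
#'
#' @inheritParams horizontal_displacement
#' @return a `displacement`.
#' @export
vertical_displacement <- function(c1, c2, side = c("left", "right"),
                                  angle_range = c("signed", "positive"),
                                  gaze = NULL) {
  side <- match.arg(side); angle_range <- match.arg(angle_range)
  check_pair(c1, c2, side)
  delta <- as.numeric(c2) - as.numeric(c1)
  d <- sqrt(delta[2]^2 + delta[3]^2)
  new_displacement(d, atan2(delta[3], delta[2]) * 180 / pi, "sagittal",
                   angle_range, side, gaze %||% attr(c2, "gaze") %||% "",
                   delta[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plane_for_gaze <- function(gaze) {
  switch(gaze, right = "axial", left = "axial", up = "sagittal",
         down = "sagittal",
         stop("no analysis plane for gaze '", gaze, "'"))
}

#' End-to-end displacement between two gazes of one subject
#'
#' Orchestrates the full measurement for one eye: segment both globes in
#' both volumes, build the static-tissue mask on the central volume,
#' register the secondary volume to it, map the secondary centroid through
#' the recovered head-motion transform (the point is transformed, never a
#' resampled mask, to preserve sub-voxel accuracy), and compute the
#' in-plane displacement for the secondary gaze's analysis plane.
#'
#' @param primary central-gaze [ot_volume()].
#' @param secondary secondary-gaze [ot_volume()] (gaze label decides the
#'   analysis plane).
#' @param side `"left"` or `"right"` eye to measure.
#' @param seed a [seed_spec()] used for all segmentations.
#' @param dilation_mm globe dilation for the static mask.
#' @param angle_range reporting convention for theta.
#' @param threshold,bounds registration acceptance controls, see
#'   [register_static()].
#' @param poles optional list `list(primary = , secondary = )` of
#'   anterior-pole landmarks (mm, each volume's own frame) enabling a
#'   rotation estimate; the phantom truth provides lens centroids.
#' @param primary_masks optional precomputed `list(left = , right = )` of
#'   `globe_mask`s for the primary volume (it is segmented afresh
#'   otherwise); useful when many secondaries share one central volume.
#' @param static_mask optional precomputed static-tissue mask for the
#'   primary volume.
#' @return a `displacement` with attributes `alignment`
#'   (the `alignment_report`), `centroids` and, when poles are given,
#'   `rotation_deg`.
#' @export
end_to_end_displacement <- function(primary, secondary,
                                    side = c("left", "right"),
                                    seed = seed_spec(),
                                    dilation_mm = 3,
                                    angle_range = c("signed", "positive"),
                                    threshold = 0.02,
                                    bounds = c(rotation = 10, translation = 10),
                                    poles = NULL, primary_masks = NULL,
                                    static_mask = NULL) {
  side <- match.arg(side); angle_range <- match.arg(angle_range)
  stage <- function(what, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))

  masks1 <- primary_masks %||%
    stage("segment primary", lapply(c(left = "left", right = "right"),
      function(s) segment_globe(primary, seed, side = s)))
  mask2 <- stage("segment secondary", segment_globe(secondary, seed, side = side))
  static <- static_mask %||%
    stage("static mask", build_static_mask(primary, masks1, dilation_mm))
  report <- stage("register",
                  register_static(secondary, primary, static,
                                  bounds = bounds, threshold = threshold))
  c1 <- centroid_mm(masks1[[side]])
  c2_raw <- centroid_mm(mask2)
  c2 <- structure(rt_apply(report$transform, as.numeric(c2_raw)),
                  names = c("x", "y", "z"), side = side,
                  gaze = secondary$gaze, class = "centroid_mm")
  plane <- plane_for_gaze(secondary$gaze)
  disp <- if (plane == "axial")
    horizontal_displacement(c1, c2, side, angle_range, gaze = secondary$gaze)
  else
    vertical_displacement(c1, c2, side, angle_range, gaze = secondary$gaze)
  attr(disp, "alignment") <- report
  attr(disp, "centroids") <- list(primary = c1, secondary_raw = c2_raw,
                                  secondary_aligned = c2)
  if (!is.null(poles)) {
    pole2 <- rt_apply(report$transform, as.numeric(poles$secondary))
    attr(disp, "rotation_deg") <- estimate_rotation_deg(
      c1, poles$primary, c2, pole2, plane)
  }
  disp
}
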