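# Synthetic multi-gaze orbital phantom.
#
# Two ellipsoidal globes (bright vitreous interior, dark scleral shell,
# dark lens) embedded in orbital fat, with bony plates and four point
# landmarks as static tissue. A secondary gaze is produced by rotating each
# globe about its own centre by the gaze angle AND translating the centre
# by a small vector (the translatory movement under study), then moving the
# whole scene by an inter-acquisition head-motion transform, then adding
# acquisition noise. Every generated quantity is recorded as ground truth
# so downstream stages can be validated by parameter recovery.

INTENSITY <- c(bone = 0.05, fat = 0.6, sclera = 0.2, vitreous = 1.0,
               lens = 0.35, landmark = 0.9)

#' Phantom configuration
#'
#' Defaults mirror the acquisition this package targets: a 256 x 256 x 67
#' grid at 0.7 x 0.7 x 0.6 mm, horizontal fixation targets at 30 deg and
#' vertical at 20 deg, and globe radius from an axial length of 25.27 mm.
#' Default true globe-centre translations are 0.7 mm along the gaze
#' direction for horizontal gaze and 0.43 mm opposite to it for vertical
#' gaze. Head motion between acquisitions is drawn uniformly within the
#' given caps (Euclidean magnitude), and noise is additive Gaussian with
#' standard deviation `noise_sd` times the vitreous intensity.
#'
#' @param grid_shape integer length 3, voxels per axis.
#' @param spacing numeric length 3, mm per axis.
#' @param axial_length axial length of the eye in mm; default globe radius
#'   is `axial_length / 2`.
#' @param globe_semi_axes numeric length 3, semi-axes (mm) of the vitreous
#'   ellipsoid; defaults to a sphere of radius `axial_length / 2`.
#' @param sclera_mm thickness of the dark scleral shell (mm).
#' @param interpupillary_offset distance of each globe centre from the
#'   midline (mm).
#' @param gaze_angles named numeric, `horizontal` and `vertical` fixation
#'   angles in degrees, each in `[0, 45]` (0 permitted for identity and
#'   rotation-null experiments).
#' @param true_translation named list of 3-vectors (mm), the true
#'   globe-centre displacement for gazes `right`, `left`, `up`, `down` in
#'   the primary patient frame.
#' @param head_motion named numeric `c(rotation = , translation = )`,
#'   magnitude caps (deg, mm) for the random inter-acquisition head motion.
#' @param noise_sd Gaussian noise SD as a fraction of vitreous intensity.
#' @param supersample integer >= 1, linear boundary-oversampling factor for
#'   partial-volume rendering and truth-mask voxelisation.
#' @param seed integer RNG seed controlling head motion and noise.
#' @return a validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(256, 256, 67),
                           spacing = c(0.7, 0.7, 0.6),
                           axial_length = 25.27,
                           globe_semi_axes = NULL,
                           sclera_mm = 1.0,
                           interpupillary_offset = 31,
                           gaze_angles = c(horizontal = 30, vertical = 20),
                           true_translation = list(
                             right = c(-0.7, 0, 0), left = c(0.7, 0, 0),
                             up = c(0, 0, -0.43), down = c(0, 0, 0.43)),
                           head_motion = c(rotation = 2, translation = 2),
                           noise_sd = 0.02,
                           supersample = 3,
                           seed = 1L) {
  if (is.null(globe_semi_axes)) globe_semi_axes <- rep(axial_length / 2, 3)
  cfg <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
              axial_length = axial_length,
              globe_semi_axes = as.numeric(globe_semi_axes),
              sclera_mm = sclera_mm,
              interpupillary_offset = interpupillary_offset,
              gaze_angles = gaze_angles, true_translation = true_translation,
              head_motion = head_motion, noise_sd = noise_sd,
              supersample = as.integer(supersample), seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (length(grid_shape) != 3 || any(grid_shape < 8))
      stop("grid_shape must be three values >= 8")
    if (any(spacing <= 0)) stop("spacing must be strictly positive")
    if (any(globe_semi_axes <= 0)) stop("degenerate globe semi-axes")
    if (supersample < 1) stop("supersample must be >= 1")
    if (noise_sd < 0 || sclera_mm < 0) stop("noise_sd and sclera_mm must be >= 0")
    if (any(gaze_angles < 0) || any(gaze_angles > 45))
      stop("gaze_angles must lie in [0, 45] degrees")
    if (!all(c("right", "left", "up", "down") %in% names(true_translation)))
      stop("true_translation must name right, left, up, down")
  })
  geom <- phantom_geometry(cfg)
  ext <- (cfg$grid_shape - 1) * cfg$spacing
  outer <- cfg$globe_semi_axes + cfg$sclera_mm
  tmax <- apply(abs(do.call(rbind, cfg$true_translation)), 2, max)
  for (side in c("left", "right")) {
    ctr <- geom$globe_center[[side]]
    lo <- ctr - max(outer) - tmax
    hi <- ctr + max(outer) + tmax
    if (any(lo < 5) || any(hi > ext - 5))
      stop("geometry error: globe (", side,
           ") does not fit in the grid with a 5 mm margin")
  }
  if (cfg$interpupillary_offset - outer[1] < 1.5)
    stop("geometry error: globes overlap the midline septum")
  invisible(cfg)
}

# fixed scene geometry in the primary patient frame (mm)
phantom_geometry <- function(cfg) {
  ext <- (cfg$grid_shape - 1) * cfg$spacing
  c0 <- ext / 2
  a <- cfg$globe_semi_axes
  outer <- a + cfg$sclera_mm
  gy <- c0[2] + 0.22 * ext[2]
  centers <- list(left = c(c0[1] + cfg$interpupillary_offset, gy, c0[3]),
                  right = c(c0[1] - cfg$interpupillary_offset, gy, c0[3]))
  orbit <- lapply(centers, function(ctr)
    list(center = ctr - c(0, 0.35 * max(a), 0), semi = outer + c(3.5, 7, 3.5)))
  lm_frac <- rbind(c(-0.55, -0.45, 0.45), c(0.6, -0.5, -0.4),
                   c(-0.45, -0.6, -0.35), c(0.5, -0.35, 0.55))
  landmarks <- lapply(seq_len(4), function(i) c0 + lm_frac[i, ] * c0)
  list(ext = ext, center = c0, globe_center = centers, semi = a,
       outer = outer, orbit = orbit, landmarks = landmarks,
       lens_semi = c(0.40, 0.28, 0.40) * max(a),
       lens_offset = 0.55 * a[2])
}

# --- scene elements: signed-distance-like membership in mm -----------------

el_ellipsoid <- function(center, semi, R = diag(3), value = 1) {
  list(type = "ellipsoid", center = center, semi = semi, R = R, value = value)
}

el_box <- function(center, halfwidth, R = diag(3), value = 1) {
  list(type = "box", center = center, halfwidth = halfwidth, R = R, value = value)
}

# approximate signed distance (mm); negative inside
element_sd <- function(el, pts) {
  u <- sweep(pts, 2, el$center, `-`) %*% el$R
  if (el$type == "ellipsoid") {
    r <- sqrt((u[, 1] / el$semi[1])^2 + (u[, 2] / el$semi[2])^2 +
              (u[, 3] / el$semi[3])^2)
    (r - 1) * min(el$semi)
  } else {
    dx <- abs(u[, 1]) - el$halfwidth[1]
    dy <- abs(u[, 2]) - el$halfwidth[2]
    dz <- abs(u[, 3]) - el$halfwidth[3]
    dx[!is.finite(dx)] <- -Inf; dy[!is.finite(dy)] <- -Inf
    dz[!is.finite(dz)] <- -Inf
    pmax(dx, dy, dz)
  }
}

# move an element rigidly: centre through tf, orientation by tf$R
transform_element <- function(el, tf) {
  el$center <- rt_apply(tf, el$center)
  el$R <- tf$R %*% el$R
  el
}

# occupancy fraction per voxel; exact 0/1 away from the boundary, boundary
# voxels resolved by an s^3 subvoxel grid
element_occupancy <- function(el, pts, spacing, supersample) {
  d <- element_sd(el, pts)
  half_diag <- 0.5 * sqrt(sum(spacing^2))
  f <- as.numeric(d < 0)
  if (supersample > 1) {
    band <- which(abs(d) <= half_diag)
    if (length(band)) {
      s <- supersample
      off1 <- (2 * seq_len(s) - s - 1) / (2 * s)
      offs <- as.matrix(expand.grid(off1 * spacing[1], off1 * spacing[2],
                                    off1 * spacing[3]))
      nb <- length(band); ns <- nrow(offs)
      sub <- pts[band, , drop = FALSE][rep(seq_len(nb), each = ns), ] +
        offs[rep(seq_len(ns), times = nb), ]
      inside <- element_sd(el, sub) < 0
      f[band] <- colMeans(matrix(inside, nrow = ns))
    }
  }
  f
}

# all voxel-centre coordinates (n x 3), x fastest
all_voxel_mm <- function(dim, spacing) {
  ax <- grid_axes(dim, spacing)
  cbind(rep(ax$x, times = dim[2] * dim[3]),
        rep(rep(ax$y, each = dim[1]), times = dim[3]),
        rep(ax$z, each = dim[1] * dim[2]))
}

render_elements <- function(elements, dim, spacing, supersample, pts = NULL) {
  if (is.null(pts)) pts <- all_voxel_mm(dim, spacing)
  img <- numeric(nrow(pts))
  for (el in elements) {
    f <- element_occupancy(el, pts, spacing, supersample)
    img <- img * (1 - f) + f * el$value
  }
  array(img, dim = dim)
}

#' Voxelise an ellipsoid on a grid
#'
#' A voxel belongs to the mask when its estimated occupancy fraction is at
#' least one half; boundary voxels are resolved with an `supersample`^3
#' subvoxel grid, so fidelity to the analytic ellipsoid improves with
#' `supersample`.
#'
#' @param center,semi ellipsoid centre and semi-axes (mm).
#' @param dim,spacing grid shape and voxel spacing.
#' @param supersample linear oversampling factor.
#' @param R ellipsoid orientation matrix.
#' @return logical 3D array.
#' @export
voxelize_ellipsoid <- function(center, semi, dim, spacing, supersample = 3,
                               R = diag(3)) {
  el <- el_ellipsoid(center, semi, R)
  f <- element_occupancy(el, all_voxel_mm(dim, spacing), spacing, supersample)
  array(f >= 0.5, dim = dim)
}

#' Partial-volume ellipsoid volume on a grid
#'
#' Sum of per-voxel occupancy fractions times the voxel volume: the
#' midpoint-rule volume estimate whose error shrinks as `supersample`
#' grows (the binarised mask of [voxelize_ellipsoid()] converges to the
#' half-occupancy voxelisation instead, whose voxel count is not exactly
#' the analytic volume at any oversampling).
#'
#' @inheritParams voxelize_ellipsoid
#' @return volume in ml.
#' @export
ellipsoid_occupancy_volume_ml <- function(center, semi, dim, spacing,
                                          supersample = 3, R = diag(3)) {
  el <- el_ellipsoid(center, semi, R)
  f <- element_occupancy(el, all_voxel_mm(dim, spacing), spacing, supersample)
  sum(f) * prod(spacing) / 1000
}

# gaze rotation descriptor: signed axis + magnitude, and the matrix
gaze_rotation <- function(gaze, angles) {
  switch(gaze,
    central = list(angle = 0, axis = c(0, 0, 1), R = diag(3)),
    right = list(angle = angles[["horizontal"]], axis = c(0, 0, 1),
                 R = euler_matrix(c(0, 0, angles[["horizontal"]]))),
    left = list(angle = angles[["horizontal"]], axis = c(0, 0, -1),
                R = euler_matrix(c(0, 0, -angles[["horizontal"]]))),
    up = list(angle = angles[["vertical"]], axis = c(1, 0, 0),
              R = euler_matrix(c(angles[["vertical"]], 0, 0))),
    down = list(angle = angles[["vertical"]], axis = c(-1, 0, 0),
                R = euler_matrix(c(-angles[["vertical"]], 0, 0))))
}

#' Generate a synthetic multi-gaze orbital phantom
#'
#' Renders one volume per requested gaze plus a ground-truth record
#' (rotation, globe-centre translation, head motion, truth masks, globe
#' centre and lens-centroid landmarks per eye, all expressed in each
#' volume's own frame). With the same seed the output is bit-identical.
#'
#' @param config a [phantom_config()].
#' @param gazes subset of `c("central","right","left","up","down")` to
#'   render; truth randomness is drawn for all five gazes in a fixed order
#'   so a subset run agrees with a full run.
#' @param head_motions optional named list of `rigid_transform`s overriding
#'   the random head motion per gaze (central is always identity).
#' @return list with `volumes` (named list of [ot_volume()]) and `truth`
#'   (per-gaze ground truth plus the config).
#' @export
generate_phantom <- function(config, gazes = GAZES, head_motions = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  gazes <- match.arg(gazes, GAZES, several.ok = TRUE)
  geom <- phantom_geometry(config)
  dimg <- config$grid_shape
  sp <- config$spacing
  c0 <- geom$center

  set.seed(config$seed)
  hm <- list()
  for (g in GAZES) {
    if (g == "central") { hm[[g]] <- rt_identity(center = c0); next }
    rot <- stats::runif(3, -1, 1); tra <- stats::runif(3, -1, 1)
    rot <- rot / sqrt(3) * config$head_motion[["rotation"]]
    tra <- tra / sqrt(3) * config$head_motion[["translation"]]
    hm[[g]] <- rigid_transform(rotation = rot, translation = tra, center = c0)
  }
  if (!is.null(head_motions))
    for (g in names(head_motions)) hm[[g]] <- head_motions[[g]]
  hm$central <- rt_identity(center = c0)

  pts <- all_voxel_mm(dimg, sp)
  volumes <- list(); truth <- list()
  for (g in gazes) {
    rotg <- gaze_rotation(g, config$gaze_angles)
    tg <- if (g == "central") c(0, 0, 0) else config$true_translation[[g]]
    H <- hm[[g]]

    static <- c(
      list(el_box(c(c0[1], c0[2], 1.25), c(Inf, Inf, 0.75),
                  value = INTENSITY["bone"]),
           el_box(c(c0[1], 1.25, c0[3]), c(Inf, 0.75, Inf),
                  value = INTENSITY["bone"]),
           el_box(c(c0[1], (c0[2] + geom$ext[2]) / 2, c0[3]),
                  c(1.0, geom$ext[2] / 4, 0.6 * c0[3]),
                  value = INTENSITY["bone"])),
      lapply(c("left", "right"), function(s)
        el_ellipsoid(geom$orbit[[s]]$center, geom$orbit[[s]]$semi,
                     value = INTENSITY["fat"])))

    eyes <- list()
    dynamic <- list()
    for (s in c("left", "right")) {
      ctr <- geom$globe_center[[s]] + tg
      sclera <- el_ellipsoid(ctr, geom$outer, R = rotg$R,
                             value = INTENSITY["sclera"])
      vitreous <- el_ellipsoid(ctr, geom$semi, R = rotg$R,
                               value = INTENSITY["vitreous"])
      lens_ctr <- ctr + as.numeric(rotg$R %*% c(0, geom$lens_offset, 0))
      lens <- el_ellipsoid(lens_ctr, geom$lens_semi, R = rotg$R,
                           value = INTENSITY["lens"])
      pole <- ctr + as.numeric(rotg$R %*% c(0, geom$semi[2], 0))
      dynamic <- c(dynamic, list(sclera, vitreous, lens))
      eyes[[s]] <- list(center_mm = rt_apply(H, ctr),
                        pole_mm = rt_apply(H, pole),
                        lens_mm = rt_apply(H, lens_ctr),
                        vitreous_el = transform_element(vitreous, H))
    }

    marks <- lapply(geom$landmarks, function(p)
      el_ellipsoid(p, rep(1.6, 3), value = INTENSITY["landmark"]))

    elements <- lapply(c(static, dynamic, marks), transform_element, tf = H)
    img <- render_elements(elements, dimg, sp, config$supersample, pts = pts)

    if (config$noise_sd > 0) {
      set.seed((config$seed * 7919 + match(g, GAZES) * 104729) %% 2147483647L)
      img <- img + array(stats::rnorm(length(img), 0,
                                      config$noise_sd * INTENSITY[["vitreous"]]),
                         dim = dimg)
    }
    volumes[[g]] <- ot_volume(img, sp, gaze = g, subject_id = "phantom")

    globe_masks <- lapply(eyes, function(e) {
      el <- e$vitreous_el
      f <- element_occupancy(el, pts, sp, config$supersample)
      array(f >= 0.5, dim = dimg)
    })
    orbit_masks <- lapply(c(left = "left", right = "right"), function(s) {
      el <- transform_element(el_ellipsoid(geom$orbit[[s]]$center,
                                           geom$orbit[[s]]$semi), H)
      f <- element_occupancy(el, pts, sp, 1L)
      array(f >= 0.5, dim = dimg)
    })
    truth[[g]] <- list(
      rotation_angle_deg = rotg$angle, rotation_axis = rotg$axis,
      translation_mm = tg, head_motion = H,
      eyes = lapply(eyes, function(e) e[c("center_mm", "pole_mm", "lens_mm")]),
      globe_mask_truth = globe_masks, orbit_mask_truth = orbit_masks)
  }
  truth$config <- config
  truth$geometry <- geom
  list(volumes = volumes, truth = truth)
}
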