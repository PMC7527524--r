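# Binary morphology and connectivity on 3D logical arrays (6-connectivity).
# Implemented with whole-array shifts so every operation is vectorised and
# deterministic; grids here are small enough that this is fast.

shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  if (abs(dx) >= d[1] || abs(dy) >= d[2] || abs(dz) >= d[3]) return(out)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

NB6 <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))

dilate6 <- function(a) {
  out <- a
  for (r in seq_len(nrow(NB6)))
    out <- out | shift3(a, NB6[r,1], NB6[r,2], NB6[r,3])
  out
}

erode6 <- function(a) {
  out <- a
  for (r in seq_len(nrow(NB6)))
    out <- out & shift3(a, NB6[r,1], NB6[r,2], NB6[r,3], fill = TRUE)
  out
}

close6 <- function(a, iterations = 1) {
  for (i in seq_len(iterations)) a <- dilate6(a)
  for (i in seq_len(iterations)) a <- erode6(a)
  a
}

# flood fill within `domain` from seed voxels (logical array of seeds)
flood_fill <- function(domain, seeds) {
  reached <- seeds & domain
  frontier <- reached
  while (any(frontier)) {
    frontier <- dilate6(frontier) & domain & !reached
    reached <- reached | frontier
  }
  reached
}

# largest 6-connected component of a logical array
largest_component <- function(a) {
  best <- NULL; best_n <- 0L
  remaining <- a
  while (any(remaining)) {
    seed_idx <- which.max(remaining)
    seeds <- array(FALSE, dim = dim(a)); seeds[seed_idx] <- TRUE
    comp <- flood_fill(remaining, seeds)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  if (is.null(best)) a else best
}

n_components <- function(a) {
  n <- 0L
  remaining <- a
  while (any(remaining)) {
    seed_idx <- which.max(remaining)
    seeds <- array(FALSE, dim = dim(a)); seeds[seed_idx] <- TRUE
    remaining <- remaining & !flood_fill(remaining, seeds)
    n <- n + 1L
  }
  n
}

# fill interior cavities: anything not reachable from the grid border
# through the background becomes foreground
fill_holes <- function(a) {
  bg <- !a
  seeds <- array(FALSE, dim = dim(a))
  seeds[c(1, dim(a)[1]), , ] <- TRUE
  seeds[, c(1, dim(a)[2]), ] <- TRUE
  seeds[, , c(1, dim(a)[3])] <- TRUE
  outside <- flood_fill(bg, seeds & bg)
  a | (bg & !outside)
}

touches_boundary <- function(a) {
  d <- dim(a)
  any(a[c(1, d[1]), , ]) || any(a[, c(1, d[2]), ]) || any(a[, , c(1, d[3])])
}

# dilation by a physical radius (mm) with an ellipsoidal structuring element
# honouring anisotropic spacing; mm = 0 is the identity
dilate_mm <- function(a, mm, spacing) {
  if (mm <= 0) return(a)
  rx <- floor(mm / spacing[1]); ry <- floor(mm / spacing[2]); rz <- floor(mm / spacing[3])
  out <- a
  for (dx in -rx:rx) for (dy in -ry:ry) for (dz in -rz:rz) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if ((dx * spacing[1])^2 + (dy * spacing[2])^2 + (dz * spacing[3])^2 > mm^2) next
    out <- out | shift3(a, dx, dy, dz)
  }
  out
}

# 3x3x3 box-mean smoothing (edge-truncated)
box3_mean <- function(a) {
  acc <- array(0, dim = dim(a)); cnt <- array(0, dim = dim(a))
  ones <- array(1, dim = dim(a))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    acc <- acc + shift3(a, dx, dy, dz, fill = 0)
    cnt <- cnt + shift3(ones, dx, dy, dz, fill = 0)
  }
  acc / cnt
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; used to score segmentations against phantom
#' ground truth.
#' @param a,b logical arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
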