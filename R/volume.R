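# Volume container and NIfTI I/O.

GAZES <- c("central", "right", "left", "up", "down")

#' Volumetric image container
#'
#' A 3D intensity grid with anisotropic voxel spacing, a gaze label and the
#' fixed internal patient-frame orientation ("LAS": +x patient left,
#' +y anterior, +z superior). Voxel `[i, j, k]` (1-based) sits at
#' `((i,j,k) - 1) * spacing` mm.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length 3, voxel spacing in mm (x, y, z); must be
#'   strictly positive.
#' @param gaze one of `"central"`, `"right"`, `"left"`, `"up"`, `"down"`.
#' @param subject_id opaque subject identifier.
#' @return an object of class `ot_volume`.
#' @export
ot_volume <- function(data, spacing, gaze = "central", subject_id = "") {
  stopifnot(is.array(data), length(dim(data)) == 3, all(dim(data) > 0))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  gaze <- match.arg(gaze, GAZES)
  structure(list(data = data, spacing = spacing, frame = "LAS",
                 gaze = gaze, subject_id = as.character(subject_id)),
            class = "ot_volume")
}

#' @export
print.ot_volume <- function(x, ...) {
  cat(sprintf("ot_volume %s: %s voxels, spacing %s mm, gaze '%s'%s\n",
              x$frame, paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x"), x$gaze,
              if (nzchar(x$subject_id)) paste0(", subject ", x$subject_id) else ""))
  invisible(x)
}

#' @export
dim.ot_volume <- function(x) dim(x$data)

#' Read a volume from a NIfTI-1 file
#'
#' Reads intensities and voxel spacing from the header and reorients the
#' data to the internal patient frame (LAS) using the header's qform/sform.
#' Files without any orientation information are assumed to already be in
#' the internal frame. Directories (DICOM series) are not supported.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param gaze,subject_id labels attached to the returned volume.
#' @return an [ot_volume()].
#' @export
read_volume <- function(path, gaze = "central", subject_id = "") {
  if (dir.exists(path))
    stop("directory input (DICOM series) is not supported; convert to NIfTI-1")
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0) {
    if (RNifti::orientation(img) != "LAS") RNifti::orientation(img) <- "LAS"
  }
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (length(spacing) < 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI header carries no usable voxel spacing: ", path)
  # pixdim is float32 on disk; drop sub-nanometre noise from the cast
  spacing <- round(spacing, 6)
  ot_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing,
            gaze = gaze, subject_id = subject_id)
}

#' Write a volume to a NIfTI-1 file
#'
#' Writes the grid losslessly (float64 for intensities, uint8 for masks)
#' with the voxel spacing and an LAS qform/sform in the header.
#'
#' @param vol an [ot_volume()], or a logical/0-1 array for `write_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"double"` is lossless for the
#'   phantoms generated here.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(inherits(vol, "ot_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- structure(diag(c(-vol$spacing[1], vol$spacing[2], vol$spacing[3], 1)),
                 code = 2L)
  RNifti::sform(img) <- m
  RNifti::qform(img) <- m
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @param spacing voxel spacing for the mask grid (mm).
#' @export
write_mask <- function(vol, path, spacing = NULL) {
  if (is.array(vol) && !inherits(vol, "ot_volume")) {
    stopifnot(!is.null(spacing))
    vol <- ot_volume(array(as.numeric(vol != 0), dim = dim(vol)), spacing)
  } else {
    vol$data <- array(as.numeric(vol$data != 0), dim = dim(vol$data))
  }
  write_volume(vol, path, datatype = "uint8")
}

#' Read a binary mask from NIfTI
#' @param path path to a mask NIfTI file.
#' @return logical 3D array with attribute `spacing`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  structure(v$data != 0, spacing = v$spacing)
}
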