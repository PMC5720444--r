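#' 3D scalar volume with physical geometry
#'
#' The universal image carrier of the package: a 3D numeric array together
#' with its voxel spacing (mm), physical origin (mm) and a modality tag.
#' Geometry follows the voxel-center convention: voxel index `(i, j, k)`
#' (1-based, as is natural in R) sits at physical position
#' `origin + (i - 1, j - 1, k - 1) * spacing`, with the third axis the slice
#' (z) axis.  Only axis-aligned geometry is supported.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel spacing in mm, all strictly positive.
#' @param origin numeric length-3, physical position (mm) of the first voxel
#'   center.
#' @param modality one of `"CT"`, `"MRI"`, `"PET"`, `"MVCT"`, `"GRID"`,
#'   `"MASK"`, `"OTHER"`.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(0, c(8, 8, 4)), spacing = c(0.8, 0.8, 7.5))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     modality = "OTHER") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume: `data` must be a 3-dimensional array")
  if (any(dim(data) < 1L)) stop("empty-shape volume is not allowed")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  modality <- match.arg(modality,
                        c("CT", "MRI", "PET", "MVCT", "GRID", "MASK", "OTHER"))
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin,
                 modality = modality),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s, %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$modality, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm; intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")

stopifnot_volume <- function(x, what = "argument") {
  if (!is_volume3d(x)) stop(sprintf("%s must be a volume3d object", what))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_geometry <- function(a, b) {
  if (!same_geometry(a, b))
    stop("volumes must share shape, spacing and origin")
  invisible(TRUE)
}

#' Binary region-of-interest mask
#'
#' A [volume3d()] whose voxel values are logical.  Converted to an intensity
#' volume, voxels inside the region have intensity exactly 1 and all others 0.
#'
#' @param data logical 3D array (or numeric, coerced by `!= 0`).
#' @inheritParams volume3d
#' @return An object of class `binary_mask` (also a `volume3d`).
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume: `data` must be a 3-dimensional array")
  mode_ok <- is.logical(data)
  lg <- if (mode_ok) data else array(data != 0, dim(data))
  v <- volume3d(array(as.double(lg), dim(lg)), spacing, origin, "MASK")
  v$data <- array(as.logical(lg), dim(lg))
  class(v) <- c("binary_mask", "volume3d")
  v
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d foreground (%.4g mm^3)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              sum(x$data), mask_volume_mm3(x)))
  invisible(x)
}

#' Physical volume of a binary mask
#'
#' @param m a [binary_mask()].
#' @return Foreground voxel count times voxel volume, in mm^3.
#' @export
mask_volume_mm3 <- function(m) {
  if (!inherits(m, "binary_mask")) stop("`m` must be a binary_mask")
  sum(m$data) * prod(m$spacing)
}

#' Convert a binary mask to a 0/1 intensity volume
#'
#' @param m a [binary_mask()].
#' @param modality modality tag of the resulting volume.
#' @return A [volume3d()] with intensity exactly 1 inside and 0 outside.
#' @export
mask_to_volume <- function(m, modality = "MASK") {
  if (!inherits(m, "binary_mask")) stop("`m` must be a binary_mask")
  volume3d(array(as.double(m$data), dim(m$data)), m$spacing, m$origin,
           modality)
}

#' Map voxel indices to physical coordinates
#'
#' @param v a [volume3d()].
#' @param idx integer vector of length 3, or an n x 3 matrix of 1-based voxel
#'   indices.
#' @return Physical mm coordinates (vector or n x 3 matrix) of the voxel
#'   centers.
#' @export
index_to_physical <- function(v, idx) {
  stopifnot_volume(v, "`v`")
  m <- if (is.matrix(idx)) idx else matrix(idx, nrow = 1)
  if (ncol(m) != 3L) stop("`idx` must have three columns")
  d <- dim(v$data)
  if (any(m < 1L) || any(m[, 1] > d[1]) || any(m[, 2] > d[2]) ||
      any(m[, 3] > d[3]))
    stop("voxel index out of range")
  out <- sweep(sweep(m - 1, 2, v$spacing, "*"), 2, v$origin, "+")
  if (is.matrix(idx)) out else drop(out)
}

#' Map physical coordinates to the nearest voxel index
#'
#' Inverse of [index_to_physical()] with nearest-integer rounding.
#'
#' @param v a [volume3d()].
#' @param pts numeric length-3 vector or n x 3 matrix of mm coordinates.
#' @return 1-based voxel indices (vector or n x 3 integer matrix).
#' @export
physical_to_index <- function(v, pts) {
  stopifnot_volume(v, "`v`")
  m <- if (is.matrix(pts)) pts else matrix(pts, nrow = 1)
  idx <- round(sweep(sweep(m, 2, v$origin, "-"), 2, v$spacing, "/")) + 1
  storage.mode(idx) <- "integer"
  d <- dim(v$data)
  if (any(idx < 1L) || any(idx[, 1] > d[1]) || any(idx[, 2] > d[2]) ||
      any(idx[, 3] > d[3]))
    stop("physical position outside the volume")
  if (is.matrix(pts)) idx else drop(idx)
}

#' Physical bounding box of a volume
#'
#' @param v a [volume3d()].
#' @return 2 x 3 matrix: mm positions of the first and last voxel centers.
#' @export
physical_extent <- function(v) {
  stopifnot_volume(v, "`v`")
  rbind(lo = v$origin, hi = v$origin + (dim(v$data) - 1) * v$spacing)
}

#' Labeled 3D point set in physical coordinates
#'
#' Points are physical mm positions tied to the geometry of a reference
#' volume; labels are unique integer identifiers.  Points outside the
#' physical bounding box of the frame are rejected.
#'
#' @param points n x 3 numeric matrix of mm coordinates.
#' @param labels integer identifiers, unique, one per point (default `1:n`).
#' @param frame a [volume3d()] supplying the reference geometry.
#' @return An object of class `pointset`.
#' @export
pointset <- function(points, labels = NULL, frame) {
  stopifnot_volume(frame, "`frame`")
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must be an n x 3 matrix")
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (is.null(labels)) labels <- seq_len(n)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("one label per point required")
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (n > 0) {
    ext <- physical_extent(frame)
    # half-voxel slack: any position inside the voxel lattice is acceptable
    lo <- ext["lo", ] - frame$spacing / 2
    hi <- ext["hi", ] + frame$spacing / 2
    inside <- points[, 1] >= lo[1] & points[, 1] <= hi[1] &
      points[, 2] >= lo[2] & points[, 2] <= hi[2] &
      points[, 3] >= lo[3] & points[, 3] <= hi[3]
    if (!all(inside))
      stop(sprintf("%d point(s) lie outside the frame bounding box",
                   sum(!inside)))
  }
  structure(list(points = points, labels = labels,
                 frame = list(shape = dim(frame$data),
                              spacing = frame$spacing,
                              origin = frame$origin)),
            class = "pointset")
}

#' @export
print.pointset <- function(x, ...) {
  cat(sprintf("<pointset> %d points in a %s frame\n", nrow(x$points),
              paste(x$frame$shape, collapse = " x ")))
  invisible(x)
}

# Rebuild an (empty) volume carrying only the frame geometry of a pointset.
frame_volume <- function(ps) {
  volume3d(array(0, ps$frame$shape), ps$frame$spacing, ps$frame$origin)
}
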