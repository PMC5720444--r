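#' Read a volume from NIfTI or NRRD
#'
#' Geometry (spacing and origin) is taken from the file header and
#' intensities are left unmodified.  Only 3D, axis-aligned volumes are
#' accepted; headers carrying a rotated (oblique) orientation are rejected
#' rather than silently ignored, because ignoring the rotation would corrupt
#' all mm distances computed downstream.
#'
#' @param path file path (`.nii`, `.nii.gz` or `.nrrd`).
#' @param format `"auto"` (from the extension), `"nifti"` or `"nrrd"`.
#' @param modality modality tag to attach (not stored in either format).
#' @return A [volume3d()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd"),
                        modality = "OTHER") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "nifti") read_nifti_volume(path, modality)
  else read_nrrd_volume(path, modality)
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
  else stop("cannot guess format from extension: ", path)
}

#' Write a volume to NIfTI or NRRD
#'
#' The written file re-reads to a volume equal to the input bit-exactly in
#' data (intensities are stored as 64-bit doubles) and to within 1e-6 mm in
#' geometry.  Binary masks are stored as 0/1 values in unsigned 8-bit
#' integers.
#'
#' @param v a [volume3d()] or [binary_mask()].
#' @param path output path; the parent directory must exist.
#' @param format `"auto"` (from the extension), `"nifti"` or `"nrrd"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = c("auto", "nifti", "nrrd")) {
  stopifnot_volume(v, "`v`")
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("cannot write volume: no such directory: ", dirname(path))
  if (format == "auto") format <- guess_format(path)
  mask <- inherits(v, "binary_mask")
  dat <- if (mask) array(as.double(v$data), dim(v$data)) else v$data
  if (format == "nifti") write_nifti_volume(dat, v, path, mask)
  else write_nrrd_volume(dat, v, path, mask)
  invisible(path)
}

read_nifti_volume <- function(path, modality) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), "D: ", path)
  m <- RNifti::xform(img)
  rot <- m[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(diag(rot))))
    stop("oblique (rotated) NIfTI orientation is not supported: ", path)
  spacing <- diag(rot)
  if (any(spacing <= 0))
    stop("non-positive or flipped spacing in NIfTI header: ", path)
  volume3d(array(as.double(img), d), spacing, m[1:3, 4], modality)
}

write_nifti_volume <- function(dat, v, path, mask) {
  dtype <- if (mask) "uint8" else "double"
  img <- RNifti::asNifti(dat, datatype = dtype)
  img <- RNifti::asNifti(img, list(
    srow_x = c(v$spacing[1], 0, 0, v$origin[1]),
    srow_y = c(0, v$spacing[2], 0, v$origin[2]),
    srow_z = c(0, 0, v$spacing[3], v$origin[3]),
    sform_code = 2L, qform_code = 0L,
    pixdim = c(1, v$spacing, 0, 0, 0, 0)))
  RNifti::writeNifti(img, path)
}

# Minimal NRRD support: detached headers are not supported; encodings are
# raw (read/write) and gzip (read); element type double (or uint8 for masks).
read_nrrd_volume <- function(path, modality) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated NRRD header: ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop("NRRD header missing field '", k, "': ", path)
    fields[[k]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("expected 3D volume: ", path)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- need("type")
  enc <- need("encoding")
  spacing <- origin <- NULL
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    m <- do.call(cbind, dirs)
    if (max(abs(m - diag(diag(m)))) > 1e-9 * max(abs(diag(m))))
      stop("oblique NRRD space directions are not supported: ", path)
    spacing <- diag(m)
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (is.null(spacing) || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NRRD header has missing or invalid spacing: ", path)
  origin <- if (!is.null(fields[["space origin"]]))
    parse_nrrd_vectors(fields[["space origin"]])[[1]] else c(0, 0, 0)
  n <- prod(sizes)
  what <- switch(type,
                 "double" = "double", "float" = "double",
                 "uchar" = "int", "unsigned char" = "int", "uint8" = "int",
                 stop("unsupported NRRD type '", type, "': ", path))
  size <- switch(type, "double" = 8L, "float" = 4L, 1L)
  raw_rest <- readBin(con, "raw", n = file.size(path))
  if (enc == "gzip") raw_rest <- memDecompress(raw_rest, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding '", enc, "': ", path)
  vals <- readBin(raw_rest, what = what, n = n, size = size,
                  endian = "little", signed = type == "double")
  if (length(vals) < n) stop("truncated NRRD data: ", path)
  volume3d(array(as.double(vals), sizes), spacing, origin, modality)
}

parse_nrrd_vectors <- function(s) {
  parts <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(parts, function(p)
    as.numeric(strsplit(gsub("[()]", "", p), ",")[[1]]))
}

write_nrrd_volume <- function(dat, v, path, mask) {
  type <- if (mask) "uint8" else "double"
  hdr <- c(
    "NRRD0004",
    "# written by regqa",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(dat), collapse = " ")),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            v$spacing[1], v$spacing[2], v$spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            v$origin[1], v$origin[2], v$origin[3]),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (mask) writeBin(as.integer(dat), con, size = 1L, endian = "little")
  else writeBin(as.vector(dat), con, size = 8L, endian = "little")
}

#' Read per-slice closed polygon contours from JSON
#'
#' Expected shape: `{"slices": [{"k": <slice index, 1-based>,
#' "points_mm": [[x, y], ...]}, ...]}`.
#'
#' @param path JSON file path.
#' @return A list of slices, each `list(k = , points_mm = <n x 2 matrix>)`,
#'   suitable for [rasterize_contours()].
#' @export
read_contours <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.null(obj$slices)) stop("contour JSON must contain a 'slices' array")
  lapply(obj$slices, function(s) {
    pm <- s$points_mm
    if (is.list(pm)) pm <- do.call(rbind, pm)
    list(k = as.integer(s$k), points_mm = matrix(as.numeric(pm), ncol = 2))
  })
}

#' Rasterize per-slice polygon contours into a binary mask
#'
#' Voxels whose centers fall strictly inside any polygon of their slice
#' (even-odd rule) are set to true.  Polygons are closed implicitly (the
#' last vertex connects back to the first).  Self-intersecting polygons are
#' accepted with a warning; the even-odd rule is still applied.
#'
#' @param slices list of `list(k = <1-based slice index>, points_mm =
#'   <n x 2 matrix of (x, y) mm vertices>)`.
#' @param frame a [volume3d()] supplying the output geometry.
#' @return A [binary_mask()] on the geometry of `frame`.
#' @export
rasterize_contours <- function(slices, frame) {
  stopifnot_volume(frame, "`frame`")
  d <- dim(frame$data)
  out <- array(FALSE, d)
  xs <- frame$origin[1] + (seq_len(d[1]) - 1) * frame$spacing[1]
  ys <- frame$origin[2] + (seq_len(d[2]) - 1) * frame$spacing[2]
  for (s in slices) {
    k <- s$k
    if (is.null(k) || k < 1 || k > d[3])
      stop("contour slice index out of range: ", k)
    poly <- s$points_mm
    if (nrow(poly) >= 2 &&
        all(abs(poly[1, ] - poly[nrow(poly), ]) < 1e-12))
      poly <- poly[-nrow(poly), , drop = FALSE]
    if (nrow(poly) < 3) stop("polygon needs at least 3 distinct vertices")
    if (polygon_self_intersects(poly))
      warning("self-intersecting polygon on slice ", k,
              "; even-odd rule applied")
    inside <- point_in_polygon_grid(xs, ys, poly)
    out[, , k] <- out[, , k] | inside
  }
  binary_mask(out, frame$spacing, frame$origin)
}

# Even-odd (crossing-number) test of every (xs[i], ys[j]) grid point against
# one polygon; vectorized over the grid, looped over edges.
point_in_polygon_grid <- function(xs, ys, poly) {
  nx <- length(xs); ny <- length(ys)
  px <- matrix(xs, nx, ny)
  py <- matrix(ys, nx, ny, byrow = TRUE)
  inside <- matrix(FALSE, nx, ny)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}
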