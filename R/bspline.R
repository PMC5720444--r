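#' Cubic B-spline free-form deformation
#'
#' A forward 3D displacement field parameterized by a regular grid of
#' cubic B-spline control-point coefficients.  The transform maps the point
#' at physical position `p` to `p + displacement(p)` (forward convention).
#' Zero coefficients give exactly zero displacement everywhere (partition of
#' unity).  Evaluation is only defined where the full 4x4x4 cubic support
#' lies inside the control grid; there is no extrapolation.
#'
#' @param coefficients numeric 4D array `(mx, my, mz, 3)` of control-point
#'   displacement coefficients in mm (last axis: x, y, z component).
#' @param control_origin mm position of control point `(1, 1, 1)`.
#' @param control_spacing mm control-point spacing, all strictly positive.
#' @return An object of class `bspline_transform`.
#' @export
bspline_transform <- function(coefficients, control_origin, control_spacing) {
  if (!is.array(coefficients) || length(dim(coefficients)) != 4L ||
      dim(coefficients)[4] != 3L)
    stop("`coefficients` must be an (mx, my, mz, 3) array")
  if (any(dim(coefficients)[1:3] < 4L))
    stop("control grid needs at least 4 points per axis (cubic support)")
  control_spacing <- as.numeric(control_spacing)
  if (length(control_spacing) != 3L || any(control_spacing <= 0))
    stop("`control_spacing` must be three strictly positive numbers (mm)")
  storage.mode(coefficients) <- "double"
  structure(list(coefficients = coefficients,
                 control_origin = as.numeric(control_origin),
                 control_spacing = control_spacing),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf("<bspline_transform> %d x %d x %d control points, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$control_spacing[1], x$control_spacing[2],
              x$control_spacing[3]))
  cat(sprintf("  max |coefficient| %.4g mm\n", max(abs(x$coefficients))))
  invisible(x)
}

coef_component <- function(t, i) {
  array(t$coefficients[, , , i], dim(t$coefficients)[1:3])
}

#' Evaluate the displacement field of a transform
#'
#' @param t a [bspline_transform()] (or any transform object).
#' @param points length-3 vector or n x 3 matrix of physical mm positions,
#'   all inside the transform support.
#' @return n x 3 matrix of mm displacements.
#' @export
displacement_at <- function(t, points) {
  pts <- if (is.matrix(points)) points else matrix(points, nrow = 1)
  transform_points(t, pts) - pts
}

#' Apply a transform to physical points
#'
#' Generic forward point map: `transform_points(t, p)` returns the images
#' of the points under `t`.  Methods exist for B-spline transforms, rigid
#' translations, lazy inverses and compositions.
#'
#' @param t a transform object.
#' @param points n x 3 matrix (or length-3 vector) of mm positions.
#' @return n x 3 matrix of mapped mm positions.
#' @export
transform_points <- function(t, points) UseMethod("transform_points")

#' @export
transform_points.bspline_transform <- function(t, points) {
  pts <- as_points_matrix(points)
  pts + cpp_bspline_disp(coef_component(t, 1), coef_component(t, 2),
                         coef_component(t, 3), t$control_origin,
                         t$control_spacing, pts)
}

as_points_matrix <- function(points) {
  m <- if (is.matrix(points)) points else matrix(points, nrow = 1)
  storage.mode(m) <- "double"
  if (ncol(m) != 3L) stop("points must be n x 3")
  m
}

#' Uniform translation transform
#'
#' @param offset length-3 mm translation vector.
#' @return A transform usable wherever a [bspline_transform()] is.
#' @export
translation_transform <- function(offset) {
  structure(list(offset = as.numeric(offset)),
            class = "translation_transform")
}

#' @export
transform_points.translation_transform <- function(t, points) {
  sweep(as_points_matrix(points), 2, t$offset, "+")
}

#' Identity transform
#' @return A transform mapping every point to itself.
#' @export
identity_transform <- function() translation_transform(c(0, 0, 0))

#' Lazy inverse of a transform
#'
#' For a B-spline transform the inverse point map is evaluated numerically
#' by fixed-point iteration on `x = y - u(x)` (tolerance `tol` mm, at most
#' `maxit` iterations per point); translations and compositions invert
#' exactly.  Inverting an inverse returns the original transform.
#'
#' @param t a transform object.
#' @param tol fixed-point convergence tolerance in mm.
#' @param maxit maximum fixed-point iterations per point.
#' @return The inverse transform.
#' @export
invert_transform <- function(t, tol = 0.01, maxit = 20L) {
  UseMethod("invert_transform")
}

#' @export
invert_transform.bspline_transform <- function(t, tol = 0.01, maxit = 20L) {
  structure(list(inner = t, tol = tol, maxit = as.integer(maxit)),
            class = "inverse_transform")
}

#' @export
invert_transform.translation_transform <- function(t, tol = 0.01, maxit = 20L) {
  translation_transform(-t$offset)
}

#' @export
invert_transform.inverse_transform <- function(t, tol = 0.01, maxit = 20L) {
  t$inner
}

#' @export
transform_points.inverse_transform <- function(t, points) {
  pts <- as_points_matrix(points)
  inner <- t$inner
  res <- cpp_bspline_invert(coef_component(inner, 1), coef_component(inner, 2),
                            coef_component(inner, 3), inner$control_origin,
                            inner$control_spacing, pts, t$tol, t$maxit)
  nfail <- sum(res$failed)
  if (nfail > 0)
    attr(res$points, "n_failed") <- nfail
  res$points
}

#' Composition of transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a` (function
#' composition `a(b(x))`).
#'
#' @param ... transform objects, outermost first.
#' @return A composed transform.
#' @export
compose_transforms <- function(...) {
  structure(list(parts = list(...)), class = "composed_transform")
}

#' @export
transform_points.composed_transform <- function(t, points) {
  pts <- as_points_matrix(points)
  for (part in rev(t$parts)) pts <- transform_points(part, pts)
  pts
}

#' @export
invert_transform.composed_transform <- function(t, tol = 0.01, maxit = 20L) {
  inv <- lapply(rev(t$parts), invert_transform, tol = tol, maxit = maxit)
  do.call(compose_transforms, inv)
}

#' Random smooth B-spline transform with zero boundary displacement
#'
#' Draws control-point coefficients i.i.d. uniform in
#' `[-max_coeff, +max_coeff]` per component, then zeroes every control
#' point whose cubic support touches the volume faces, so the displacement
#' vanishes identically in a one-control-spacing band inside each face
#' (anatomy fixed at the field-of-view boundary).  The control grid covers
#' the full physical extent of `frame` plus the cubic support margin.
#'
#' @param frame a [volume3d()] whose extent the transform must cover.
#' @param control_spacing control-point spacing in mm (scalar or length 3);
#'   must be at least 4x the largest in-plane voxel spacing.
#' @param max_coeff coefficient amplitude in mm; 0 gives the identity.
#' @param seed integer RNG seed (mandatory; no hidden global RNG state).
#' @return A [bspline_transform()].
#' @export
random_transform <- function(frame, control_spacing = 32, max_coeff = 5,
                             seed) {
  stopifnot_volume(frame, "`frame`")
  if (missing(seed)) stop("`seed` is required")
  control_spacing <- rep(as.numeric(control_spacing), length.out = 3)
  if (any(control_spacing <= 0)) stop("`control_spacing` must be positive")
  if (any(control_spacing[1:2] < 4 * max(frame$spacing[1:2])))
    stop("control spacing must be at least 4x the in-plane voxel spacing")
  if (max_coeff < 0) stop("`max_coeff` must be nonnegative")
  geo <- bspline_grid_for(frame, control_spacing)
  m <- geo$shape
  coef <- array(0, c(m, 3))
  rng <- with_seed(seed, array(stats::runif(prod(m) * 3, -max_coeff,
                                            max_coeff), c(m, 3)))
  # free interior region: zero 5 layers on each side so the displacement
  # vanishes identically in a one-control-spacing band inside each face
  zb <- 5L
  if (any(m <= 2 * zb)) {
    if (max_coeff > 0)
      stop("frame extent must be at least ~6 control spacings per axis ",
           "for a boundary-zeroed transform; reduce `control_spacing`")
  } else {
    ix <- (zb + 1):(m[1] - zb); iy <- (zb + 1):(m[2] - zb)
    iz <- (zb + 1):(m[3] - zb)
    coef[ix, iy, iz, ] <- rng[ix, iy, iz, ]
  }
  bspline_transform(coef, geo$origin, control_spacing)
}

# Control grid covering the frame extent with the cubic support margin.
bspline_grid_for <- function(frame, control_spacing) {
  ext <- physical_extent(frame)
  origin <- ext["lo", ] - 2 * control_spacing
  shape <- as.integer(ceiling((ext["hi", ] - ext["lo", ]) / control_spacing) + 5)
  list(origin = origin, shape = shape)
}

#' Scale a B-spline transform
#'
#' Multiplies every coefficient by `factor`; by linearity of the spline the
#' displacement field scales exactly linearly.
#'
#' @param t a [bspline_transform()].
#' @param factor nonnegative scalar.
#' @return The scaled transform.
#' @export
scale_transform <- function(t, factor) {
  if (!inherits(t, "bspline_transform"))
    stop("`t` must be a bspline_transform")
  if (factor < 0) stop("`factor` must be nonnegative")
  bspline_transform(t$coefficients * factor, t$control_origin,
                    t$control_spacing)
}

de_from_residuals <- function(res) {
  c(de_mm = sqrt(mean(rowSums(res^2))),
    axial_de_mm = sqrt(mean(rowSums(res[, 1:2, drop = FALSE]^2))))
}

#' True displacement error of a transform at sampled points
#'
#' RMS displacement over the sample: `de = sqrt(mean |t(x_i) - x_i|^2)`;
#' the axial value uses only the in-plane (x, y) components.
#'
#' @param t a transform object.
#' @param sample_points a [pointset()] inside the transform support.
#' @return Named vector `c(de_mm, axial_de_mm)`.
#' @export
true_de <- function(t, sample_points) {
  if (!inherits(sample_points, "pointset"))
    stop("`sample_points` must be a pointset")
  if (nrow(sample_points$points) == 0) stop("empty point set")
  res <- displacement_at(t, sample_points$points)
  de_from_residuals(res)
}

#' True displacement error over every voxel of a frame
#'
#' Exact dense evaluation of the RMS displacement (3D and in-plane) over
#' all voxel centers of `frame`, computed in compiled code.
#'
#' @param t a [bspline_transform()].
#' @param frame a [volume3d()] inside the transform support.
#' @return Named vector `c(de_mm, axial_de_mm, max_mm)`.
#' @export
true_de_dense <- function(t, frame) {
  if (!inherits(t, "bspline_transform"))
    stop("`t` must be a bspline_transform")
  stopifnot_volume(frame, "`frame`")
  v <- cpp_de_dense(coef_component(t, 1), coef_component(t, 2),
                    coef_component(t, 3), t$control_origin,
                    t$control_spacing, dim(frame$data), frame$spacing,
                    frame$origin)
  c(de_mm = v[1], axial_de_mm = v[2], max_mm = v[3])
}

#' Residual displacement error of a recovered transform
#'
#' Composes the recovered transform with the known forward transform and
#' evaluates the residual `e_i = |t_rec(t0(x_i)) - x_i|` at the sampled
#' points; perfect recovery (`t_rec` the exact inverse along the sampled
#' trajectory) gives zero.  Points whose forward image leaves the recovered
#' transform's support are excluded and counted; more than 10% exclusions is
#' an error.
#'
#' @param t0 the known forward transform.
#' @param t_rec the recovered transform (e.g. a registration output).
#' @param sample_points a [pointset()].
#' @return Named list with `de_mm`, `axial_de_mm`, `n_used`, `n_excluded`.
#' @export
compose_residual <- function(t0, t_rec, sample_points) {
  if (!inherits(sample_points, "pointset"))
    stop("`sample_points` must be a pointset")
  x <- sample_points$points
  if (nrow(x) == 0) stop("empty point set")
  fwd <- transform_points(t0, x)
  back <- tryCatch(transform_points(t_rec, fwd), error = function(e) NULL)
  if (is.null(back)) {
    # per-point fallback when some forward images leave support
    back <- matrix(NA_real_, nrow(x), 3)
    for (i in seq_len(nrow(x))) {
      back[i, ] <- tryCatch(transform_points(t_rec, fwd[i, , drop = FALSE]),
                            error = function(e) c(NA_real_, NA, NA))
    }
  }
  ok <- stats::complete.cases(back)
  n_exc <- sum(!ok)
  if (n_exc > 0.1 * nrow(x))
    stop(sprintf("%d of %d points exited the transform support", n_exc,
                 nrow(x)))
  res <- back[ok, , drop = FALSE] - x[ok, , drop = FALSE]
  out <- as.list(de_from_residuals(res))
  out$n_used <- sum(ok)
  out$n_excluded <- n_exc
  out
}

#' Warp a volume with a forward transform
#'
#' Backward resampling: the output voxel at physical position `y` takes the
#' trilinearly interpolated source intensity at `t^{-1}(y)`.  For B-spline
#' transforms the inverse map is evaluated by fixed-point iteration
#' (tolerance 0.01 mm, at most 20 iterations per voxel); if more than 0.1%
#' of voxels fail to converge the deformation is too strong to invert and
#' an error is raised.  Voxels pulling from outside the field of view
#' receive `pad`.
#'
#' @param v a [volume3d()].
#' @param t a transform object covering `v`.
#' @param pad padding intensity for out-of-field voxels.
#' @return The warped [volume3d()].
#' @export
warp_volume <- function(v, t, pad = 0) {
  stopifnot_volume(v, "`v`")
  inv <- invert_transform(t)
  d <- dim(v$data)
  out <- array(0, d)
  xs <- v$origin[1] + (seq_len(d[1]) - 1) * v$spacing[1]
  ys <- v$origin[2] + (seq_len(d[2]) - 1) * v$spacing[2]
  n_fail <- 0
  slab <- cbind(rep(xs, times = d[2]), rep(ys, each = d[1]), 0)
  for (k in seq_len(d[3])) {
    slab[, 3] <- v$origin[3] + (k - 1) * v$spacing[3]
    src <- transform_points(inv, slab)
    nf <- attr(src, "n_failed")
    if (!is.null(nf)) n_fail <- n_fail + nf
    out[, , k] <- cpp_resample_trilinear(v$data, d, v$spacing, v$origin,
                                         src, pad)
  }
  if (n_fail > 0.001 * prod(d))
    stop(sprintf(paste0("inverse-map iteration failed at %d of %d voxels; ",
                        "the deformation is too strong to invert reliably"),
                 n_fail, prod(d)))
  volume3d(out, v$spacing, v$origin, v$modality)
}

#' Write a B-spline transform to JSON
#'
#' @param t a [bspline_transform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path) {
  if (!inherits(t, "bspline_transform"))
    stop("only bspline_transform objects can be serialized")
  obj <- list(control_origin = t$control_origin,
              control_spacing = t$control_spacing,
              grid_shape = dim(t$coefficients)[1:3],
              coefficients = as.vector(t$coefficients),
              convention = "forward_mm")
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Read a B-spline transform from JSON
#'
#' @param path JSON path written by [write_transform()].
#' @return A [bspline_transform()].
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(as.character(obj$convention), "forward_mm"))
    stop("unsupported transform convention in ", path)
  shape <- as.integer(obj$grid_shape)
  bspline_transform(array(as.numeric(obj$coefficients), c(shape, 3L)),
                    obj$control_origin, obj$control_spacing)
}
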