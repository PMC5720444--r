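#' Black-box registration system contract
#'
#' A black-box system exposes only `register(source, target, setting)`
#' returning an opaque handle, and `apply(handle, volume)` resampling any
#' geometry-compatible volume through the stored deformation.  The
#' deformation function itself is never accessible; a handle can be stored
#' and reapplied, and reapplication is deterministic.
#'
#' @param register_fn function `(source, target, setting, ...)` returning a
#'   [registration_handle()].
#' @param settings character vector of supported setting ids.
#' @param name system name for provenance records.
#' @return An object of class `black_box_system`.
#' @export
black_box_system <- function(register_fn, settings = setting_grid(),
                             name = "system") {
  structure(list(register_fn = register_fn, settings = settings,
                 name = name),
            class = "black_box_system")
}

#' Register a source image to a target image
#'
#' @param system a [black_box_system()].
#' @param source,target [volume3d()] objects on the same geometry.
#' @param setting a setting id from `system$settings`.
#' @param ... passed through to the system (mock systems receive the truth
#'   transform of a synthetic study through `truth = `; real systems
#'   ignore it).
#' @return A [registration_handle()].
#' @export
system_register <- function(system, source, target, setting, ...) {
  if (!inherits(system, "black_box_system"))
    stop("`system` must be a black_box_system")
  if (!setting %in% system$settings)
    stop("unknown setting '", setting, "'")
  h <- system$register_fn(source, target, setting, ...)
  if (!inherits(h, "registration_handle"))
    stop("system register_fn must return a registration_handle")
  h
}

#' Opaque registration handle
#'
#' Wraps the stored deformation of one registration together with its
#' provenance.  Consumers may only call [system_apply()] on it.
#'
#' @param transform the transform to replay (opaque to consumers).
#' @param provenance named list (system, setting, ids).
#' @return An object of class `registration_handle`.
#' @export
registration_handle <- function(transform, provenance = list()) {
  structure(list(transform = transform, provenance = provenance),
            class = "registration_handle")
}

#' Apply a stored registration to a volume
#'
#' Deterministic image-in/image-out resampling of `v` through the stored
#' deformation, exactly as a commercial system reapplies a saved
#' registration to the original source or any other image.
#'
#' @param handle a [registration_handle()].
#' @param v a [volume3d()].
#' @param pad padding intensity for out-of-field voxels.
#' @return The resampled [volume3d()].
#' @export
system_apply <- function(handle, v, pad = 0) {
  if (!inherits(handle, "registration_handle"))
    stop("`handle` must be a registration_handle")
  warp_volume(v, handle$transform, pad = pad)
}

#' Mock black-box system replaying the known truth
#'
#' A test double for a commercial system: registration of a synthetic pair
#' "recovers" the exact inverse of the true transform (passed by the study
#' harness as `truth = `), optionally composed with an injected residual
#' transform per setting.  Zero injected residual makes
#' apply-after-forward-map the identity on probe truth, so the mock bounds
#' the protocol's detection noise floor from below.
#'
#' @param residuals named list mapping setting ids to residual transforms
#'   (or a single transform applied for every setting); `NULL` means exact
#'   recovery.
#' @param settings supported setting ids.
#' @return A [black_box_system()].
#' @export
mock_system <- function(residuals = NULL, settings = "default") {
  register_fn <- function(source, target, setting, ..., truth = NULL) {
    if (is.null(truth))
      stop("mock_system requires the study harness to supply `truth`")
    rec <- invert_transform(truth)
    res <- if (is.null(residuals)) NULL
    else if (inherits(residuals, "bspline_transform") ||
             inherits(residuals, "translation_transform")) residuals
    else residuals[[setting]]
    tr <- if (is.null(res)) rec else compose_transforms(res, rec)
    registration_handle(tr, list(system = "mock", setting = setting))
  }
  black_box_system(register_fn, settings = settings, name = "mock")
}

#' Minimal reference free-form-deformation registrar
#'
#' Gradient descent on the sum of squared differences over cubic B-spline
#' displacement coefficients, with step halving whenever a step would
#' increase the objective (so the SSD trajectory is non-increasing by
#' construction) and a snapshot of the transform after every iteration.
#' Registration quality is deliberately modest: the registrar's role in
#' the validation protocol is to produce graded, smooth, data-driven
#' deformations (each iterate is a plausible deformation magnitude), not
#' to compete with production registration algorithms.
#'
#' The returned transforms map positions in the target domain to their
#' corresponding source positions: if `target` was produced as
#' `warp_volume(source, t)`, the snapshots converge toward the point map
#' of `t` itself; conversely, registering a synthetic image back to the
#' baseline it was warped from recovers the forward warp, whose lazy
#' inverse is the stored deformation a black-box system would replay (see
#' [ffd_system()]).
#'
#' @param source,target [volume3d()] objects on identical geometry.
#' @param control_spacing control-point spacing in mm.
#' @param max_iters number of gradient iterations (>= 1).
#' @param step initial step size as maximum coefficient change per
#'   iteration, mm.
#' @param smooth_vox Gaussian pre-smoothing of both images in voxels;
#'   smoothing removes the interpolation kinks that otherwise lock a
#'   sharp-edged image pair at the aligned lattice configuration.
#' @return List of [bspline_transform()] snapshots (one per iteration)
#'   with attribute `ssd`, the objective value after each iteration.
#' @export
reference_ffd_register <- function(source, target, control_spacing = 32,
                                   max_iters = 10, step = 2,
                                   smooth_vox = 1) {
  stopifnot_volume(source, "`source`"); stopifnot_volume(target, "`target`")
  check_same_geometry(source, target)
  if (max_iters < 1) stop("`max_iters` must be at least 1")
  control_spacing <- rep(as.numeric(control_spacing), length.out = 3)
  geo <- bspline_grid_for(source, control_spacing)
  m <- geo$shape
  coef <- list(x = array(0, m), y = array(0, m), z = array(0, m))
  d <- dim(source$data)
  sdat <- source$data
  tdat <- target$data
  if (smooth_vox > 0) {
    sdat <- cpp_blur_gaussian(sdat, d, rep(smooth_vox, 3))
    tdat <- cpp_blur_gaussian(tdat, d, rep(smooth_vox, 3))
  }
  eval_ssd <- function(cf, want_grad) {
    cpp_ffd_ssd_grad(sdat, tdat, d, source$spacing,
                     source$origin, cf$x, cf$y, cf$z, geo$origin,
                     control_spacing, want_grad)
  }
  cur <- eval_ssd(coef, TRUE)
  snapshots <- vector("list", max_iters)
  ssds <- numeric(max_iters)
  scale <- NULL
  for (it in seq_len(max_iters)) {
    gmax <- max(abs(cur$gx), abs(cur$gy), abs(cur$gz))
    if (gmax == 0) {
      snapshots[[it]] <- make_snapshot(coef, geo, control_spacing)
      ssds[it] <- cur$ssd
      next
    }
    # warm-start the step from the previous iteration's accepted scale
    scale <- if (is.null(scale)) step / gmax else scale * 2
    halvings <- 0
    repeat {
      cand <- list(x = coef$x - scale * cur$gx,
                   y = coef$y - scale * cur$gy,
                   z = coef$z - scale * cur$gz)
      nxt <- eval_ssd(cand, TRUE)
      if (nxt$ssd <= cur$ssd) break
      halvings <- halvings + 1
      if (halvings > 40)
        stop("reference registrar diverged: objective will not descend")
      scale <- scale / 2
    }
    coef <- cand
    cur <- nxt
    snapshots[[it]] <- make_snapshot(coef, geo, control_spacing)
    ssds[it] <- cur$ssd
  }
  attr(snapshots, "ssd") <- ssds
  snapshots
}

#' Black-box system backed by the reference registrar
#'
#' Wraps [reference_ffd_register()] in the [black_box_system()] contract:
#' `register` runs the registrar and stores the lazy inverse of its final
#' snapshot as the replayable deformation, exactly how an opaque system
#' stores a transform for later reapplication.  The single setting id is
#' `"reference"`.
#'
#' @param control_spacing,max_iters,step,smooth_vox passed to
#'   [reference_ffd_register()].
#' @return A [black_box_system()].
#' @export
ffd_system <- function(control_spacing = 32, max_iters = 10, step = 2,
                       smooth_vox = 1) {
  register_fn <- function(source, target, setting, ...) {
    snaps <- reference_ffd_register(source, target,
                                    control_spacing = control_spacing,
                                    max_iters = max_iters, step = step,
                                    smooth_vox = smooth_vox)
    registration_handle(invert_transform(snaps[[length(snaps)]]),
                        list(system = "reference_ffd", setting = setting))
  }
  black_box_system(register_fn, settings = "reference",
                   name = "reference_ffd")
}

make_snapshot <- function(coef, geo, control_spacing) {
  m <- dim(coef$x)
  arr <- array(0, c(m, 3))
  arr[, , , 1] <- coef$x; arr[, , , 2] <- coef$y; arr[, , , 3] <- coef$z
  bspline_transform(arr, geo$origin, control_spacing)
}

#' Intra-modality absolute validation study
#'
#' For each known transform `t0`: deform the baseline into a synthetic
#' image, register the synthetic image back to the baseline on the system
#' under test, forward-splat a fresh grid probe with `t0`, push the
#' deformed grid through the system's stored deformation (image in, image
#' out), and measure the residual displacement error against the planted
#' truth.  `pre` columns hold the known pre-registration displacement
#' error (dense Eq.-style RMS of `t0`); `post` columns hold the grid-probe
#' estimate after recovery.
#'
#' @param baseline a [volume3d()].
#' @param transform_family list of [bspline_transform()]s, graded in
#'   magnitude.
#' @param system a [black_box_system()].
#' @param setting setting id to use.
#' @param n_points grid-probe density.
#' @param seed base seed for grid generation.
#' @param warp_baseline when `FALSE` the synthetic image rendering is
#'   skipped (mock systems recover from the truth transform and never look
#'   at the images); the probe pipeline is identical either way.
#' @return data.frame with columns `pre_de`, `post_de`, `pre_axial`,
#'   `post_axial`, `fraction_matched`, `unreliable`.
#' @export
run_intramodality_study <- function(baseline, transform_family, system,
                                    setting = system$settings[1],
                                    n_points = 1000, seed = 1,
                                    warp_baseline = TRUE) {
  stopifnot_volume(baseline, "`baseline`")
  rows <- list()
  for (ti in seq_along(transform_family)) {
    t0 <- transform_family[[ti]]
    pre <- true_de_dense(t0, baseline)
    synthetic <- if (warp_baseline) warp_volume(baseline, t0) else baseline
    handle <- system_register(system, synthetic, baseline, setting,
                              truth = t0)
    g <- make_grid_image(baseline, n_points, seed = seed + ti)
    deformed <- suppressWarnings(splat_forward(g, t0))
    recovered <- system_apply(handle, deformed$volume)
    rep <- approximate_de(g, recovered)
    rows[[length(rows) + 1L]] <- data.frame(
      transform = ti,
      pre_de = unname(pre["de_mm"]), post_de = rep$de_mm,
      pre_axial = unname(pre["axial_de_mm"]), post_axial = rep$axial_de_mm,
      fraction_matched = rep$fraction_matched,
      unreliable = rep$unreliable)
  }
  do.call(rbind, rows)
}

#' Inter-modality absolute validation study
#'
#' Registers the source image to the target image, pushes the binarized
#' source mask through the stored deformation (as a 0/1 intensity image),
#' re-binarizes at 0.5, and reports contour overlap metrics before and
#' after registration.
#'
#' @param source,target [volume3d()] objects.
#' @param system a [black_box_system()].
#' @param setting setting id.
#' @param mask_source,mask_target [binary_mask()] objects on the
#'   source/target geometry.
#' @param ... passed to [system_register()] (e.g. `truth = ` for mocks).
#' @return List of class `intermodality_result` with `pre` and `post`
#'   [contour_metrics()].
#' @export
run_intermodality_study <- function(source, target, system, setting,
                                    mask_source, mask_target, ...) {
  handle <- system_register(system, source, target, setting, ...)
  warped <- system_apply(handle, mask_to_volume(mask_source))
  post_mask <- binary_from_volume(warped, 0.5)
  if (sum(post_mask$data) == 0)
    stop("post-registration mask is empty")
  structure(list(pre = contour_metrics(mask_source, mask_target),
                 post = contour_metrics(post_mask, mask_target)),
            class = "intermodality_result")
}

#' Relative validation: rank settings by post-registration similarity
#'
#' Registers every case under every setting, applies the stored
#' deformation to the source, scores the deformed source against the
#' target with a similarity metric, and ranks settings by per-setting mean
#' metric.
#'
#' @param cases list of `list(source = , target = , ...)`; extra elements
#'   (e.g. `truth`) are forwarded to the system's register call.
#' @param system a [black_box_system()].
#' @param settings setting ids to compare (default: all of the system's).
#' @param metric scoring function `(warped, target) -> scalar`, higher
#'   better (default [nmi()]).
#' @return List with `ranking` (a [rank_settings()] result) and `scores`
#'   (the raw per-setting per-case data.frame).
#' @export
run_relative_validation <- function(cases, system,
                                    settings = system$settings,
                                    metric = nmi) {
  rows <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    extra <- cs[setdiff(names(cs), c("source", "target"))]
    for (s in settings) {
      handle <- do.call(system_register,
                        c(list(system, cs$source, cs$target, s), extra))
      warped <- system_apply(handle, cs$source)
      rows[[length(rows) + 1L]] <- data.frame(
        setting = s, case = ci, value = metric(warped, cs$target))
    }
  }
  scores <- do.call(rbind, rows)
  list(ranking = rank_settings(scores), scores = scores)
}
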