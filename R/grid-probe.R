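#' Nonuniform grid probe image
#'
#' An otherwise-zero volume with sparse unit-intensity voxels at randomly
#' chosen, well-separated voxel centers, paired with the exact subvoxel mm
#' positions and labels of the planted points.  Such images let residual
#' displacements be measured through an opaque image-in/image-out
#' registration pipeline: the system never sees the truth, only the image.
#'
#' @param frame a [volume3d()] supplying the geometry.
#' @param n_points number of planted points (>= 1).
#' @param seed integer RNG seed (mandatory).
#' @param min_separation minimum pairwise mm distance between planted
#'   points; defaults to 3 in-plane voxels, which limits merging at the
#'   recommended 1000-point density.
#' @param max_attempts rejection-sampling budget.
#' @return An object of class `grid_image`: `list(volume, truth)` where
#'   `truth` is a [pointset()].
#' @export
make_grid_image <- function(frame, n_points, seed,
                            min_separation = 3 * max(frame$spacing[1:2]),
                            max_attempts = 1e6) {
  stopifnot_volume(frame, "`frame`")
  if (missing(seed)) stop("`seed` is required")
  if (n_points < 1) stop("`n_points` must be at least 1")
  d <- dim(frame$data)
  sel <- with_seed(seed, {
    accepted <- matrix(0L, n_points, 3)
    # spatial hash on cells of edge >= min_separation for O(1) checks
    cell <- pmax(min_separation, frame$spacing)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    n_acc <- 0L; attempts <- 0L
    while (n_acc < n_points) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("cannot place ", n_points, " points at separation ",
             min_separation, " mm: packing infeasible")
      idx <- c(sample.int(d[1], 1), sample.int(d[2], 1), sample.int(d[3], 1))
      p <- frame$origin + (idx - 1) * frame$spacing
      cp <- floor(p / cell)
      ok <- TRUE
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        key <- paste(cp[1] + dx, cp[2] + dy, cp[3] + dz)
        prev <- seen[[key]]
        if (!is.null(prev)) {
          for (q in prev) {
            if (sum((q - p)^2) < min_separation^2) { ok <- FALSE; break }
          }
        }
        if (!ok) break
      }
      if (!ok) next
      n_acc <- n_acc + 1L
      accepted[n_acc, ] <- idx
      key <- paste(cp[1], cp[2], cp[3])
      seen[[key]] <- c(seen[[key]], list(p))
    }
    accepted
  })
  dat <- array(0, d)
  dat[sel] <- 1
  pts <- index_to_physical(frame, sel)
  g <- list(volume = volume3d(dat, frame$spacing, frame$origin, "GRID"),
            truth = pointset(pts, seq_len(n_points), frame))
  class(g) <- "grid_image"
  g
}

#' @export
print.grid_image <- function(x, ...) {
  cat(sprintf("<grid_image> %d planted points in a %s frame\n",
              nrow(x$truth$points),
              paste(dim(x$volume$data), collapse = " x ")))
  invisible(x)
}

#' Forward-splat a grid image through a transform
#'
#' Each planted point of mass is moved to its forward image under `t` and
#' deposited with trilinear weights onto the 8 voxels surrounding the
#' mapped subvoxel position, preserving both total intensity and the first
#' moment (the centroid of each deposit equals the mapped position
#' exactly).  Truth positions are updated to the mapped positions.  Points
#' mapping outside the frame are dropped with a warning; more than 10%
#' dropped is an error.
#'
#' @param g a [make_grid_image()] result.
#' @param t a transform object.
#' @return A new `grid_image`; the number of dropped points is available as
#'   `attr(, "n_excluded")`.
#' @export
splat_forward <- function(g, t) {
  if (!inherits(g, "grid_image")) stop("`g` must be a grid_image")
  v <- g$volume
  d <- dim(v$data)
  mapped <- transform_points(t, g$truth$points)
  f <- sweep(sweep(mapped, 2, v$origin, "-"), 2, v$spacing, "/")
  i0 <- floor(f)
  frac <- f - i0
  # a deposit is kept only when every stencil voxel carrying nonzero weight
  # falls inside the frame (points exactly on a face voxel center are fine)
  ax_ok <- function(a) (i0[, a] >= 0 | (i0[, a] == -1 & frac[, a] == 1)) &
    (i0[, a] + 1 <= d[a] - 1 | (i0[, a] == d[a] - 1 & frac[, a] == 0))
  keep <- ax_ok(1) & ax_ok(2) & ax_ok(3)
  n_exc <- sum(!keep)
  if (n_exc > 0.1 * nrow(mapped))
    stop(sprintf("%d of %d grid points mapped outside the frame",
                 n_exc, nrow(mapped)))
  if (n_exc > 0)
    warning(sprintf("%d grid point(s) mapped outside the frame and were dropped",
                    n_exc))
  fk <- f[keep, , drop = FALSE]
  ik <- i0[keep, , drop = FALSE]
  a <- fk - ik
  out <- array(0, d)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx) a[, 1] else 1 - a[, 1]) *
      (if (cy) a[, 2] else 1 - a[, 2]) *
      (if (cz) a[, 3] else 1 - a[, 3])
    lin <- (ik[, 1] + cx + 1) + (ik[, 2] + cy) * d[1] +
      (ik[, 3] + cz) * d[1] * d[2]
    nz <- w > 0                 # zero-weight taps may index outside the frame
    if (!any(nz)) next
    # accumulate (several points can hit the same voxel)
    acc <- rowsum(w[nz], lin[nz])
    out[as.numeric(rownames(acc))] <- out[as.numeric(rownames(acc))] + acc[, 1]
  }
  res <- list(volume = volume3d(out, v$spacing, v$origin, "GRID"),
              truth = pointset(mapped[keep, , drop = FALSE],
                               g$truth$labels[keep], v))
  class(res) <- "grid_image"
  attr(res, "n_excluded") <- n_exc
  res
}

#' Detect grid points in a volume
#'
#' Thresholds the image, labels 26-connected components and returns one
#' intensity-weighted centroid (mm) per component.  Labels follow the
#' lexicographic order of each component's first voxel.
#'
#' @param v a [volume3d()] (typically a rendered grid image).
#' @param threshold detection threshold; defaults to 5% of the maximum
#'   intensity, separating trilinear deposit tails from the zero background.
#' @return A [pointset()]; empty when nothing exceeds the threshold.
#' @export
detect_points <- function(v, threshold = NULL) {
  stopifnot_volume(v, "`v`")
  if (is.null(threshold)) threshold <- 0.05 * max(v$data)
  idx <- which(v$data > threshold)
  if (length(idx) == 0)
    return(pointset(matrix(numeric(0), 0, 3), integer(0), v))
  d <- dim(v$data)
  coords <- arrayInd(idx, d)
  labels <- cpp_label_components(coords - 1L, d)
  w <- v$data[idx]
  pos <- index_to_physical(v, coords)
  wsum <- rowsum(w, labels)
  cx <- rowsum(w * pos[, 1], labels) / wsum
  cy <- rowsum(w * pos[, 2], labels) / wsum
  cz <- rowsum(w * pos[, 3], labels) / wsum
  pts <- cbind(cx, cy, cz)
  dimnames(pts) <- NULL
  out <- pointset(pts, seq_along(wsum), v)
  # total component intensity: for splatted unit-mass probes the (near
  # integer) mass reveals how many planted points a component absorbed
  attr(out, "mass") <- as.numeric(wsum)
  out
}

#' Match detected points to reference points
#'
#' Mutual-nearest-neighbor pairing within `max_radius`: a reference and a
#' detection are paired only if each is the other's nearest neighbor and
#' the second-nearest candidate of each is more than `ambiguity_ratio`
#' times farther away.  Pairs failing the ratio test are discarded as
#' ambiguous (the merging/crossover failure mode of dense grids); all
#' bookkeeping is reported.
#'
#' @param reference a [pointset()] of true positions.
#' @param detected a [pointset()] of detections in the same frame.
#' @param max_radius maximum pairing distance in mm.
#' @param ambiguity_ratio required second-to-first nearest distance ratio.
#' @return An object of class `match_result` with elements `pairs`
#'   (data.frame: `label`, `ref_*`, `det_*` mm), `n_unmatched_truth`,
#'   `n_unmatched_detected`, `n_ambiguous_discarded`.
#' @export
match_points <- function(reference, detected, max_radius = 15,
                         ambiguity_ratio = 1.5) {
  if (!inherits(reference, "pointset") || !inherits(detected, "pointset"))
    stop("`reference` and `detected` must be pointsets")
  nr <- nrow(reference$points); nd <- nrow(detected$points)
  empty <- data.frame(label = integer(0), ref_x = numeric(0),
                      ref_y = numeric(0), ref_z = numeric(0),
                      det_x = numeric(0), det_y = numeric(0),
                      det_z = numeric(0))
  if (nr == 0 || nd == 0) {
    return(structure(list(pairs = empty, n_unmatched_truth = nr,
                          n_unmatched_detected = nd,
                          n_ambiguous_discarded = 0L),
                     class = "match_result"))
  }
  dm <- pairwise_dist(reference$points, detected$points)
  nn_det <- apply(dm, 1, which.min)          # per reference
  nn_ref <- apply(dm, 2, which.min)          # per detection
  d1_ref <- dm[cbind(seq_len(nr), nn_det)]
  mutual <- nn_ref[nn_det] == seq_len(nr) & d1_ref <= max_radius
  second_ok <- function(drow, j) {
    if (length(drow) < 2) return(TRUE)
    d2 <- min(drow[-j])
    d2 > ambiguity_ratio * drow[j] || drow[j] == 0 && d2 > 0
  }
  amb <- 0L
  sel <- logical(nr)
  for (i in which(mutual)) {
    j <- nn_det[i]
    ok <- second_ok(dm[i, ], j) && second_ok(dm[, j], i)
    if (ok) sel[i] <- TRUE else amb <- amb + 1L
  }
  pairs <- data.frame(label = reference$labels[sel],
                      ref_x = reference$points[sel, 1],
                      ref_y = reference$points[sel, 2],
                      ref_z = reference$points[sel, 3],
                      det_x = detected$points[nn_det[sel], 1],
                      det_y = detected$points[nn_det[sel], 2],
                      det_z = detected$points[nn_det[sel], 3])
  structure(list(pairs = pairs,
                 n_unmatched_truth = nr - nrow(pairs) - amb,
                 n_unmatched_detected = nd -
                   length(unique(nn_det[sel])),
                 n_ambiguous_discarded = amb),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs, %d truth unmatched, %d detections unmatched, %d ambiguous discarded\n",
              nrow(x$pairs), x$n_unmatched_truth, x$n_unmatched_detected,
              x$n_ambiguous_discarded))
  invisible(x)
}

#' Deformation-coherent point matching
#'
#' Matching for grids deformed by a smooth field whose displacements can
#' exceed the inter-point spacing, where raw nearest-neighbor pairing
#' breaks down.  The matcher alternates an entropic optimal-transport soft
#' correspondence (Sinkhorn iterations, annealed temperature) with a
#' Gaussian kernel-ridge fit of the displacement field implied by the soft
#' correspondence; the annealing resolves the global assignment while the
#' field fit enforces spatial coherence.  Detected component masses act as
#' transport capacities, so a component that absorbed two merged probe
#' points legitimately receives both.  The final hard assignment is a
#' greedy capacity-respecting pairing on the compensated distances; pairs
#' whose compensated residual still exceeds `max_radius` are discarded as
#' ambiguous.  Smoothness of the deformation is the only assumption about
#' the field.
#'
#' @inheritParams match_points
#' @param max_radius hard-assignment radius (mm) on displacement-
#'   compensated distances.
#' @param kernel_hi,kernel_lo annealing range (mm) of the Gaussian
#'   bandwidth of the displacement-field smoother; `kernel_lo` should be
#'   about half the control spacing of the expected deformation.
#' @param eps_hi,eps_lo annealing range (mm^2) of the entropic
#'   regularization temperature.
#' @param iterations number of anneal/re-fit rounds.
#' @param ridge ridge regularization of the kernel fit.
#' @param max_fit_points subsample size for the kernel fit on dense grids.
#' @return A `match_result`, as for [match_points()], with an extra
#'   element `n_shared`: the number of pairs that share a multi-point
#'   (merged) detection.
#' @export
match_points_coherent <- function(reference, detected, max_radius = 10,
                                  kernel_hi = 45, kernel_lo = 14,
                                  eps_hi = 60, eps_lo = 1.5,
                                  iterations = 12, ridge = 0.02,
                                  max_fit_points = 2000) {
  if (!inherits(reference, "pointset") || !inherits(detected, "pointset"))
    stop("`reference` and `detected` must be pointsets")
  ref <- reference$points
  det <- detected$points
  nr <- nrow(ref); nd <- nrow(det)
  if (nr == 0 || nd == 0)
    return(match_points(reference, detected, max_radius))
  mass <- attr(detected, "mass")
  cap <- if (is.null(mass)) rep(1L, nd) else pmax(1L, as.integer(round(mass)))
  u <- matrix(0, nr, 3)
  fit_idx <- if (nr > max_fit_points)
    round(seq(1, nr, length.out = max_fit_points)) else seq_len(nr)
  D2ff <- pairwise_dist2(ref[fit_idx, , drop = FALSE],
                         ref[fit_idx, , drop = FALSE])
  D2af <- pairwise_dist2(ref, ref[fit_idx, , drop = FALSE])
  for (it in seq_len(iterations)) {
    fr <- (it - 1) / max(1, iterations - 1)
    sig <- kernel_hi * (kernel_lo / kernel_hi)^fr
    eps <- eps_hi * (eps_lo / eps_hi)^fr
    P <- sinkhorn_rows(pairwise_dist2(ref + u, det), as.numeric(cap), eps)
    disp <- P %*% det - ref
    Kff <- exp(-D2ff / (2 * sig^2))
    alpha <- solve(Kff + ridge * diag(length(fit_idx)),
                   disp[fit_idx, , drop = FALSE])
    u <- exp(-D2af / (2 * sig^2)) %*% alpha
  }
  hard_assign_capacity(reference, detected, ref + u, cap, max_radius)
}

# Entropic OT plan between unit-mass rows and capacity-weighted columns,
# returned row-normalized (barycentric weights).  D2 in squared mm.
sinkhorn_rows <- function(D2, colmass, eps, iters = 40) {
  K <- exp(-sweep(D2, 1, apply(D2, 1, min)) / eps)
  K[K < 1e-300] <- 1e-300
  v <- rep(1, ncol(D2))
  u <- NULL
  for (s in seq_len(iters)) {
    u <- 1 / (K %*% v)
    v <- colmass / crossprod(K, u)[, 1]
  }
  P <- K * (u[, 1] %o% v)
  P / pmax(rowSums(P), 1e-12)
}

# Greedy ascending-distance one-to-capacity hard assignment between
# compensated predictions and detections; deterministic.
hard_assign_capacity <- function(reference, detected, pred, cap, max_radius) {
  ref <- reference$points; det <- detected$points
  dm <- sqrt(pairwise_dist2(pred, det))
  cand <- which(dm <= max_radius, arr.ind = TRUE)
  ord <- order(dm[cand])
  cand <- cand[ord, , drop = FALSE]
  nc <- nrow(cand)
  usedr <- logical(nrow(ref)); left <- cap
  ri <- integer(nc); di <- integer(nc); np <- 0L
  for (k in seq_len(nc)) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!usedr[i] && left[j] > 0L) {
      usedr[i] <- TRUE; left[j] <- left[j] - 1L
      np <- np + 1L; ri[np] <- i; di[np] <- j
    }
  }
  ri <- ri[seq_len(np)]; di <- di[seq_len(np)]
  pairs <- data.frame(label = reference$labels[ri],
                      ref_x = ref[ri, 1], ref_y = ref[ri, 2],
                      ref_z = ref[ri, 3],
                      det_x = det[di, 1], det_y = det[di, 2],
                      det_z = det[di, 3])
  shared <- di %in% which(cap > 1L)
  structure(list(pairs = pairs,
                 n_unmatched_truth = nrow(ref) - np,
                 n_unmatched_detected = sum(!seq_len(nrow(det)) %in% di),
                 n_ambiguous_discarded = 0L,
                 n_shared = sum(shared)),
            class = "match_result")
}

pairwise_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

pairwise_dist <- function(a, b) sqrt(pairwise_dist2(a, b))

#' Approximate displacement error from a grid probe
#'
#' The black-box measurement: detect points in the output image, match them
#' against the planted truth of `before`, and evaluate the RMS residual over
#' matched pairs (and its in-plane component).  The estimate is a sample
#' approximation; the matched fraction is reported, results with fewer than
#' half the points matched are an error, and estimates with a matched
#' fraction below 0.8 are flagged `unreliable`.
#'
#' @param before the undeformed [make_grid_image()] carrying the truth.
#' @param after_recovery [volume3d()]: the pipeline output image (for a
#'   perfect system, a rendering of `before`).
#' @param threshold detection threshold, see [detect_points()].
#' @param max_radius matching radius in mm, see [match_points()].
#' @param method `"mutual_nn"` (the conservative default, suited to the
#'   small residuals left after registration recovery) or `"coherent"`
#'   (see [match_points_coherent()]; required when the measured field's
#'   displacements are comparable to the probe spacing).
#' @return An object of class `de_report`: `de_mm`, `axial_de_mm`,
#'   `n_points_used`, `fraction_matched`, `unreliable`, `match`.
#' @export
approximate_de <- function(before, after_recovery, threshold = NULL,
                           max_radius = 15,
                           method = c("mutual_nn", "coherent")) {
  method <- match.arg(method)
  if (!inherits(before, "grid_image")) stop("`before` must be a grid_image")
  v <- if (is_volume3d(after_recovery)) after_recovery
       else if (inherits(after_recovery, "grid_image")) after_recovery$volume
       else stop("`after_recovery` must be a volume3d")
  det <- detect_points(v, threshold)
  mt <- if (method == "coherent")
    match_points_coherent(before$truth, det,
                          max_radius = min(max_radius, 10))
  else match_points(before$truth, det, max_radius)
  n_truth <- nrow(before$truth$points)
  frac <- nrow(mt$pairs) / n_truth
  if (frac < 0.5)
    stop(sprintf("only %.0f%% of grid points matched; estimate unreliable",
                 100 * frac))
  res <- as.matrix(mt$pairs[, c("det_x", "det_y", "det_z")]) -
    as.matrix(mt$pairs[, c("ref_x", "ref_y", "ref_z")])
  de <- de_from_residuals(res)
  structure(list(de_mm = unname(de[1]), axial_de_mm = unname(de[2]),
                 n_points_used = nrow(mt$pairs), fraction_matched = frac,
                 unreliable = frac < 0.8, match = mt),
            class = "de_report")
}

#' @export
print.de_report <- function(x, ...) {
  cat(sprintf("<de_report> DE %.3f mm (axial %.3f mm) from %d points (%.1f%% matched%s)\n",
              x$de_mm, x$axial_de_mm, x$n_points_used,
              100 * x$fraction_matched,
              if (isTRUE(x$unreliable)) "; UNRELIABLE" else ""))
  invisible(x)
}

#' Grid-probe accuracy study
#'
#' Self-validation of the estimator: for each known transform and each grid
#' density, plant a grid, forward-splat it with the transform, then measure
#' the displacement error of the deformed grid against the planted truth
#' through the full detect/match pipeline, and tabulate the measurement
#' against the exact per-point displacement-error aggregate of the
#' transform over the planted truth (the quantity the probe estimates),
#' with the dense whole-frame RMS recorded alongside for context.  This
#' quantifies the combined detection and correspondence error of the probe
#' over a graded family of deformations; the grid pipeline never sees the
#' transform, only the two images.
#'
#' @param frame a [volume3d()] geometry.
#' @param transforms list of [bspline_transform()]s, graded in magnitude.
#' @param n_points_options vector of grid densities to test.
#' @param seed integer; per-grid seeds are derived deterministically.
#' @param min_separation passed to [make_grid_image()].
#' @return data.frame with one row per (transform, density): `n_points`,
#'   `true_de`, `measured_de`, `true_axial`, `measured_axial` (mm, over
#'   the planted sample), `dense_de`, `dense_axial` (mm, whole frame),
#'   `fraction_matched` and `n_faults` (unmatched + ambiguity-discarded +
#'   merged-shared points).
#' @export
accuracy_study <- function(frame, transforms, n_points_options = 1000,
                           seed = 1,
                           min_separation = 3 * max(frame$spacing[1:2])) {
  rows <- list()
  for (ti in seq_along(transforms)) {
    t0 <- transforms[[ti]]
    dense <- true_de_dense(t0, frame)
    for (ni in seq_along(n_points_options)) {
      np <- n_points_options[ni]
      g <- make_grid_image(frame, np, seed = seed + 1000L * ti + ni,
                           min_separation = min_separation)
      truth <- true_de(t0, g$truth)
      def <- suppressWarnings(splat_forward(g, t0))
      rep <- approximate_de(g, def$volume, method = "coherent")
      mt <- rep$match
      n_shared <- if (is.null(mt$n_shared)) 0L else mt$n_shared
      rows[[length(rows) + 1L]] <- data.frame(
        transform = ti, n_points = np,
        true_de = unname(truth["de_mm"]),
        measured_de = rep$de_mm,
        true_axial = unname(truth["axial_de_mm"]),
        measured_axial = rep$axial_de_mm,
        dense_de = unname(dense["de_mm"]),
        dense_axial = unname(dense["axial_de_mm"]),
        fraction_matched = rep$fraction_matched,
        n_faults = mt$n_unmatched_truth + mt$n_ambiguous_discarded +
          n_shared)
    }
  }
  do.call(rbind, rows)
}
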