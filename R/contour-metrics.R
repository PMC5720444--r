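#' Tannimoto coefficient (intersection over union)
#'
#' `|A intersect B| / |A union B|` by voxel counting: 1 for perfect
#' agreement between volumes, 0 for no overlap.
#'
#' @param a,b [binary_mask()] objects on identical geometry, not both empty.
#' @return Scalar in `[0, 1]`.
#' @export
tannimoto <- function(a, b) {
  ov <- overlap_counts(a, b)
  ov$inter / ov$union
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; algebraically `2 TC / (1 + TC)`.
#'
#' @inheritParams tannimoto
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  ov <- overlap_counts(a, b)
  2 * ov$inter / (ov$na + ov$nb)
}

overlap_counts <- function(a, b) {
  if (!inherits(a, "binary_mask") || !inherits(b, "binary_mask"))
    stop("arguments must be binary_mask objects")
  check_same_geometry(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) stop("overlap of two empty masks is undefined")
  inter <- sum(a$data & b$data)
  list(na = na, nb = nb, inter = inter, union = na + nb - inter)
}

#' Symmetric mean surface distance between two masks
#'
#' Surface voxels are foreground voxels with at least one background
#' 6-neighbor (the volume faces count as background).  The metric is the
#' average of the two directed means of nearest-surface-voxel-center
#' Euclidean distances, in mm.
#'
#' @inheritParams tannimoto
#' @return Nonnegative scalar (mm); 0 exactly for identical masks.
#' @export
mean_surface_distance <- function(a, b) {
  if (!inherits(a, "binary_mask") || !inherits(b, "binary_mask"))
    stop("arguments must be binary_mask objects")
  check_same_geometry(a, b)
  sa <- surface_points(a)
  sb <- surface_points(b)
  if (nrow(sa) == 0 || nrow(sb) == 0)
    stop("mean surface distance of an empty mask is undefined")
  (mean(cpp_min_dists(sa, sb)) + mean(cpp_min_dists(sb, sa))) / 2
}

# mm coordinates of surface voxel centers (6-connectivity complement test).
surface_points <- function(m) {
  d <- dim(m$data)
  x <- m$data
  shift_bg <- function(axis, dir) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (dir > 0) {
      idx_dst[[axis]] <- seq_len(d[axis] - 1)
      idx_src[[axis]] <- 2:d[axis]
    } else {
      idx_dst[[axis]] <- 2:d[axis]
      idx_src[[axis]] <- seq_len(d[axis] - 1)
    }
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(do.call(`[`, c(list(x), idx_src)))))
    out
  }
  # neighbor-is-foreground indicator; faces (missing neighbors) stay FALSE
  all_nb_fg <- array(TRUE, d)
  for (axis in 1:3) for (dir in c(-1, 1))
    all_nb_fg <- all_nb_fg & shift_bg(axis, dir)
  surf <- x & !all_nb_fg
  idx <- which(surf)
  if (length(idx) == 0) return(matrix(numeric(0), 0, 3))
  coords <- arrayInd(idx, d)
  sweep(sweep((coords - 1), 2, m$spacing, "*"), 2, m$origin, "+")
}

#' Threshold a volume into a binary mask
#'
#' For re-binarizing warped 0/1 images after interpolation the default
#' threshold of 0.5 keeps the mask volume approximately invariant.
#'
#' @param v a [volume3d()].
#' @param threshold voxels with intensity `>= threshold` become foreground.
#' @return A [binary_mask()].
#' @export
binary_from_volume <- function(v, threshold = 0.5) {
  stopifnot_volume(v, "`v`")
  binary_mask(v$data >= threshold, v$spacing, v$origin)
}

#' Full contour-metric report for a mask pair
#'
#' @inheritParams tannimoto
#' @return A list of class `contour_metrics`: `tc`, `dsc`,
#'   `mean_surface_distance_mm`, `vol_a_mm3`, `vol_b_mm3`.
#' @export
contour_metrics <- function(a, b) {
  structure(list(tc = tannimoto(a, b), dsc = dice(a, b),
                 mean_surface_distance_mm = mean_surface_distance(a, b),
                 vol_a_mm3 = mask_volume_mm3(a),
                 vol_b_mm3 = mask_volume_mm3(b)),
            class = "contour_metrics")
}

#' @export
print.contour_metrics <- function(x, ...) {
  cat(sprintf("<contour_metrics> TC %.3f | DSC %.3f | MSD %.2f mm | volumes %.0f / %.0f mm^3\n",
              x$tc, x$dsc, x$mean_surface_distance_mm, x$vol_a_mm3,
              x$vol_b_mm3))
  invisible(x)
}
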