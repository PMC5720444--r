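#' Joint intensity histogram of a registered image pair
#'
#' Equal-width 2D binning over each image's robust intensity range (0.5th
#' to 99.5th percentile by default; `range_policy = "full"` uses the full
#' min-max range).  Intensities outside the range are clamped into the
#' extreme bins, so counts always sum to the overlap voxel count.  All
#' voxels of the shared grid are included; no background masking is
#' applied, so similarity gains driven by structures away from the region
#' of interest (couch, body outline) are measurable rather than hidden.
#'
#' @param a,b [volume3d()] objects on identical geometry.
#' @param bins number of bins per axis (>= 2).
#' @param range_policy `"robust"` or `"full"`.
#' @return `bins` x `bins` count matrix with attributes `breaks_a`,
#'   `breaks_b`.
#' @export
joint_histogram <- function(a, b, bins = 64, range_policy = c("robust",
                                                              "full")) {
  stopifnot_volume(a, "`a`"); stopifnot_volume(b, "`b`")
  check_same_geometry(a, b)
  range_policy <- match.arg(range_policy)
  if (bins < 2) stop("`bins` must be at least 2")
  ia <- bin_index(as.vector(a$data), bins, range_policy)
  ib <- bin_index(as.vector(b$data), bins, range_policy)
  counts <- matrix(0, bins, bins)
  tab <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins)
  counts[] <- tab
  structure(counts, breaks_a = attr(ia, "breaks"),
            breaks_b = attr(ib, "breaks"))
}

bin_index <- function(x, bins, range_policy) {
  r <- if (range_policy == "robust")
    stats::quantile(x, c(0.005, 0.995), names = FALSE) else range(x)
  if (r[1] >= r[2]) r <- c(r[1] - 0.5, r[1] + 0.5)  # constant image
  breaks <- seq(r[1], r[2], length.out = bins + 1)
  idx <- findInterval(x, breaks, all.inside = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > bins] <- bins
  structure(idx, breaks = breaks)
}

hist_probs <- function(h) {
  p <- h / sum(h)
  list(p = p, pa = rowSums(p), pb = colSums(p))
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

check_nondegenerate <- function(pr) {
  if (entropy_bits(pr$pa) == 0 || entropy_bits(pr$pb) == 0)
    stop("degenerate (zero-entropy) image: similarity undefined")
}

#' Normalized mutual information
#'
#' Studholme's overlap-invariant form `(H(A) + H(B)) / H(A, B)` with
#' entropies in bits, computed from the joint histogram.  Identical
#' non-constant images give exactly 2; independent images approach 1.
#'
#' @inheritParams joint_histogram
#' @return Scalar in `[1, 2]` (up to estimation noise).
#' @export
nmi <- function(a, b, bins = 64) {
  pr <- hist_probs(joint_histogram(a, b, bins))
  check_nondegenerate(pr)
  (entropy_bits(pr$pa) + entropy_bits(pr$pb)) / entropy_bits(pr$p)
}

#' Mutual information in bits
#'
#' `sum p(a,b) log2(p(a,b) / (p(a) p(b)))` over the joint histogram.
#'
#' @inheritParams joint_histogram
#' @return Nonnegative scalar (bits).
#' @export
mutual_information <- function(a, b, bins = 64) {
  pr <- hist_probs(joint_histogram(a, b, bins))
  check_nondegenerate(pr)
  entropy_bits(pr$pa) + entropy_bits(pr$pb) - entropy_bits(pr$p)
}

#' Pearson correlation coefficient over the overlap domain
#'
#' Intended for intra-modality pairs only; for inter-modality pairs the
#' linear-intensity assumption does not hold and the value should be
#' excluded from analysis.
#'
#' @param a,b [volume3d()] objects on identical geometry, both with nonzero
#'   intensity variance.
#' @return Scalar in `[-1, 1]`.
#' @export
correlation_coefficient <- function(a, b) {
  stopifnot_volume(a, "`a`"); stopifnot_volume(b, "`b`")
  check_same_geometry(a, b)
  if (stats::var(as.vector(a$data)) == 0 ||
      stats::var(as.vector(b$data)) == 0)
    stop("zero-variance image: correlation undefined")
  stats::cor(as.vector(a$data), as.vector(b$data))
}

#' Symmetric correlation ratio
#'
#' Average of the two directed correlation ratios
#' `eta^2(A|B) = Var(E[A | B-bin]) / Var(A)` computed from the joint
#' histogram: 1 when either image is a deterministic function of the other
#' (given bins that resolve the levels), near 0 for independent images.
#'
#' @inheritParams joint_histogram
#' @return Scalar in `[0, 1]`.
#' @export
symmetric_correlation_ratio <- function(a, b, bins = 64) {
  stopifnot_volume(a, "`a`"); stopifnot_volume(b, "`b`")
  check_same_geometry(a, b)
  av <- as.vector(a$data); bv <- as.vector(b$data)
  if (stats::var(av) == 0 || stats::var(bv) == 0)
    stop("zero-variance image: correlation ratio undefined")
  ia <- bin_index(av, bins, "robust")
  ib <- bin_index(bv, bins, "robust")
  (eta_sq(av, ib) + eta_sq(bv, ia)) / 2
}

# Var(E[x | g]) / Var(x), population variances.
eta_sq <- function(x, g) {
  n <- length(x)
  mu <- mean(x)
  cnt <- tabulate(g)
  keep <- cnt > 0
  means <- rowsum(x, g)[, 1] / cnt[keep]
  sum(cnt[keep] * (means - mu)^2) / sum((x - mu)^2)
}

#' Build a full similarity report for one image pair
#'
#' @inheritParams joint_histogram
#' @param inter_modality when `TRUE` the correlation coefficient is not
#'   computed (its linear-intensity assumption fails across modalities).
#' @return A list of class `similarity_report`: `nmi`, `mi_bits`, `scr`,
#'   `cc` (or `NA` when flagged inter-modality), `n_voxels_overlap`, `bins`.
#' @export
similarity_report <- function(a, b, bins = 64, inter_modality = FALSE) {
  structure(list(
    nmi = nmi(a, b, bins),
    mi_bits = mutual_information(a, b, bins),
    scr = symmetric_correlation_ratio(a, b, bins),
    cc = if (inter_modality) NA_real_ else correlation_coefficient(a, b),
    n_voxels_overlap = length(a$data),
    bins = bins), class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> NMI %.4f | MI %.4f bits | SCR %.4f | CC %s (%d voxels, %d bins)\n",
              x$nmi, x$mi_bits, x$scr,
              if (is.na(x$cc)) "-" else sprintf("%.4f", x$cc),
              x$n_voxels_overlap, x$bins))
  invisible(x)
}

#' Rank registration settings by mean metric value
#'
#' Ranks settings by their per-case mean metric, rank 1 being the highest
#' mean (best).  Every setting must be scored on the same cases; ties are
#' broken lexicographically by setting id and flagged.
#'
#' @param results data.frame with columns `setting`, `case`, `value`.
#' @return data.frame of class `setting_ranking` with columns `setting`,
#'   `mean_value`, `rank`, `tied`.
#' @export
rank_settings <- function(results) {
  need <- c("setting", "case", "value")
  if (!all(need %in% names(results)))
    stop("`results` must have columns setting, case, value")
  tab <- table(results$setting, results$case)
  if (any(tab != 1)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    if (nrow(miss) > 0)
      stop("missing cells: ",
           paste(sprintf("%s/%s", rownames(tab)[miss[, 1]],
                         colnames(tab)[miss[, 2]]), collapse = ", "))
    stop("duplicated (setting, case) measurements")
  }
  means <- tapply(results$value, results$setting, mean)
  ord <- order(-means, names(means))
  out <- data.frame(setting = names(means)[ord],
                    mean_value = as.numeric(means[ord]),
                    rank = seq_along(means))
  out$tied <- duplicated(out$mean_value) |
    duplicated(out$mean_value, fromLast = TRUE)
  class(out) <- c("setting_ranking", "data.frame")
  out
}

#' Names of the 36 registration setting permutations
#'
#' All combinations of stiffness (None, Soft, Medium, Stiff), speed (Slow,
#' Medium, Fast) and refinement (Coarse, Medium, Fine), in
#' `Stiffness-Speed-Refinement` order, e.g. `"St-Sl-Fi"`.
#'
#' @return Character vector of 36 setting ids.
#' @export
setting_grid <- function() {
  g <- expand.grid(refinement = c("Co", "Me", "Fi"),
                   speed = c("Sl", "Me", "Fa"),
                   stiffness = c("No", "So", "Me", "St"),
                   stringsAsFactors = FALSE)
  paste(g$stiffness, g$speed, g$refinement, sep = "-")
}
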