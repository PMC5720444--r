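#' Export a phantom scenario to disk
#'
#' Writes `{name}_{modality}_{source|target}.nii.gz` volumes for every
#' modality pair plus `{name}_truth.json` holding the modification ground
#' truth (sphere id, change type, displacement in mm), so downstream
#' registration evaluations have an absolute reference.
#'
#' @param scenario a [scenario_pair()] result.
#' @param dir output directory (created if missing).
#' @param name scenario name used as the filename stem.
#' @return Character vector of written paths, invisibly.
#' @export
export_scenario <- function(scenario, dir, name = "scenario") {
  if (!inherits(scenario, "phantom_scenario"))
    stop("`scenario` must come from scenario_pair()")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (p in scenario$pairs) {
    for (role in c("source", "target")) {
      fn <- file.path(dir, sprintf("%s_%s_%s.nii.gz", name,
                                   tolower(p$modality), role))
      write_volume(p[[role]], fn)
      paths <- c(paths, fn)
    }
  }
  ch <- scenario$truth$change
  truth <- list(change = class(ch)[1], sphere_id = ch$id,
                displacement_mm = scenario$truth$displacement_mm)
  if (!is.null(ch$vector)) truth$vector_mm <- ch$vector
  if (!is.null(ch$new_radius)) truth$new_radius_mm <- ch$new_radius
  tf <- file.path(dir, sprintf("%s_truth.json", name))
  jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tf))
}

#' Write an axial overlay image of two volumes
#'
#' Renders one axial slice with the target in grayscale and the source in
#' a red overlay, the standard fused display used for qualitative
#' registration review.  Requires the `png` package.
#'
#' @param source,target [volume3d()] objects on identical geometry.
#' @param path output PNG path.
#' @param k slice index (default: middle slice).
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(source, target, path, k = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for overlay export")
  check_same_geometry(source, target)
  d <- dim(target$data)
  if (is.null(k)) k <- max(1L, round(d[3] / 2))
  norm01 <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) array(0, dim(x)) else (x - r[1]) / (r[2] - r[1])
  }
  tg <- norm01(target$data[, , k])
  sc <- norm01(source$data[, , k])
  img <- array(0, c(d[2], d[1], 3))
  # transpose so y runs down the image rows
  img[, , 1] <- t(pmin(1, 0.5 * tg + 0.7 * sc))
  img[, , 2] <- t(0.5 * tg)
  img[, , 3] <- t(0.5 * tg)
  png::writePNG(img, path)
  invisible(path)
}
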