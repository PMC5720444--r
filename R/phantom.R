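#' Digital multimodality phantom specification
#'
#' A cylindrical water phantom with a water-equivalent plastic base slab
#' (carrying the threaded hole grid used to position targets), a plastic
#' cylinder wall, and solid plastic spheres distributed through the water
#' volume.  The cylinder axis is the z (slice) axis, centered at the
#' in-plane origin.  Spheres must lie fully inside the water volume and
#' must not intersect each other.  Mounting rods are not modelled.
#'
#' @param cylinder_radius outer cylinder radius in mm (including the wall).
#' @param cylinder_height cylinder height in mm (z from 0 to height).
#' @param base_slab_thickness plastic slab thickness at the cylinder base,
#'   mm.
#' @param shell_thickness plastic cylinder-wall thickness, mm; the wall
#'   gives no signal on modalities where plastic is signal-free.
#' @param hole_grid `list(n = , pitch_mm = )`: the hole grid of the base
#'   slab (geometry bookkeeping for sphere placement; holes are not
#'   rendered).
#' @param spheres data.frame with columns `id`, `x`, `y`, `z`, `radius`
#'   (mm, sphere centers and radii).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(cylinder_radius = 100, cylinder_height = 120,
                         base_slab_thickness = 15, shell_thickness = 3,
                         hole_grid = list(n = 12, pitch_mm = 8),
                         spheres = default_spheres()) {
  spec <- structure(list(cylinder_radius = cylinder_radius,
                         cylinder_height = cylinder_height,
                         base_slab_thickness = base_slab_thickness,
                         shell_thickness = shell_thickness,
                         hole_grid = hole_grid,
                         spheres = spheres),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# Seven spheres of graded radius, placed on the base-slab hole grid pitch,
# spread through the water volume.
default_spheres <- function() {
  data.frame(
    id = 1:7,
    x = c(-48, 0, 48, -24, 24, -48, 40),
    y = c(-48, -40, -48, 8, 8, 48, 48),
    z = c(40, 60, 80, 45, 75, 60, 40),
    radius = c(5, 7.5, 10, 12.5, 15, 9, 6))
}

validate_phantom_spec <- function(spec) {
  problems <- character(0)
  if (spec$cylinder_radius <= 0) problems <- c(problems, "cylinder_radius <= 0")
  if (spec$cylinder_height <= 0) problems <- c(problems, "cylinder_height <= 0")
  if (spec$hole_grid$pitch_mm <= 0) problems <- c(problems, "hole pitch <= 0")
  if (spec$shell_thickness < 0) problems <- c(problems, "shell_thickness < 0")
  s <- spec$spheres
  rin <- spec$cylinder_radius - spec$shell_thickness
  for (i in seq_len(nrow(s))) {
    r2d <- sqrt(s$x[i]^2 + s$y[i]^2)
    if (r2d + s$radius[i] > rin)
      problems <- c(problems,
                    sprintf("sphere %d exits the water cylinder", s$id[i]))
    if (s$z[i] - s$radius[i] < spec$base_slab_thickness ||
        s$z[i] + s$radius[i] > spec$cylinder_height)
      problems <- c(problems,
                    sprintf("sphere %d exits the water column in z", s$id[i]))
  }
  if (nrow(s) > 1) {
    for (i in seq_len(nrow(s) - 1)) for (j in (i + 1):nrow(s)) {
      d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 +
                  (s$z[i] - s$z[j])^2)
      if (d < s$radius[i] + s$radius[j])
        problems <- c(problems, sprintf("spheres %d and %d intersect",
                                        s$id[i], s$id[j]))
    }
  }
  if (length(problems) > 0)
    stop("invalid phantom spec: ", paste(problems, collapse = "; "))
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> cylinder r=%.0f mm h=%.0f mm, %d spheres (radii %.1f-%.1f mm)\n",
              x$cylinder_radius, x$cylinder_height, nrow(x$spheres),
              min(x$spheres$radius), max(x$spheres$radius)))
  invisible(x)
}

#' Modality acquisition model for phantom rendering
#'
#' Maps materials to intensities and applies the system's resolution as an
#' isotropic Gaussian point-spread function plus additive Gaussian noise.
#'
#' @param modality `"CT"`, `"MRI"` or `"PET"`.
#' @param intensities named list `list(water = , plastic = , air = )`.
#' @param psf_fwhm point-spread FWHM in mm (>= 0).
#' @param noise_sigma additive Gaussian noise standard deviation (>= 0).
#' @param shape image matrix (3 integers).
#' @param spacing voxel spacing mm (3 values).
#' @return An object of class `modality_model`.
#' @export
modality_model <- function(modality, intensities, psf_fwhm, noise_sigma,
                           shape, spacing) {
  if (psf_fwhm < 0 || noise_sigma < 0)
    stop("psf_fwhm and noise_sigma must be nonnegative")
  structure(list(modality = modality, intensities = intensities,
                 psf_fwhm = psf_fwhm, noise_sigma = noise_sigma,
                 shape = as.integer(shape), spacing = as.numeric(spacing)),
            class = "modality_model")
}

#' Default CT / MRI / PET phantom acquisition models
#'
#' Intensity maps: CT in approximate HU (water 0, water-equivalent plastic
#' +120, air -1000); T1 MRI with signal from water only (plastic and air
#' are signal voids); PET activity in the water (FDG solution) with cold
#' plastic and air.  PSF FWHMs of 0.7, 0.8 and 6.5 mm reflect typical CT,
#' MRI and PET system resolutions.  Default grids are scaled-down
#' acquisition matrices; pass `shape`/`spacing` for full-size renders.
#'
#' @param shape,spacing optional overrides of the image grid.
#' @return A [modality_model()].
#' @name default_models
NULL

#' @rdname default_models
#' @export
ct_model <- function(shape = c(128, 128, 31), spacing = c(1.8, 1.8, 4.0)) {
  modality_model("CT", list(water = 0, plastic = 120, air = -1000),
                 psf_fwhm = 0.7, noise_sigma = 10, shape = shape,
                 spacing = spacing)
}

#' @rdname default_models
#' @export
mri_model <- function(shape = c(128, 128, 21), spacing = c(1.8, 1.8, 6.0)) {
  modality_model("MRI", list(water = 1000, plastic = 0, air = 0),
                 psf_fwhm = 0.8, noise_sigma = 20, shape = shape,
                 spacing = spacing)
}

#' @rdname default_models
#' @export
pet_model <- function(shape = c(72, 72, 30), spacing = c(4, 4, 4)) {
  modality_model("PET", list(water = 1, plastic = 0, air = 0),
                 psf_fwhm = 6.5, noise_sigma = 0.02, shape = shape,
                 spacing = spacing)
}

# Signed-distance-style occupancy of each material class at the voxel
# centers, with 2x2x2 supersampling of boundary voxels for partial volume.
phantom_material_occupancy <- function(spec, model) {
  d <- model$shape
  sp <- model$spacing
  # center the cylinder in-plane; z from 0 at the first slice
  origin <- c(-(d[1] - 1) / 2 * sp[1], -(d[2] - 1) / 2 * sp[2], 0)
  frame <- volume3d(array(0, d), sp, origin)
  xs <- axis_coords(frame, 1); ys <- axis_coords(frame, 2)
  zs <- axis_coords(frame, 3)
  occ_plastic <- array(0, d)
  occ_water <- array(0, d)
  sub <- as.matrix(expand.grid(x = c(-0.25, 0.25), y = c(-0.25, 0.25),
                               z = c(-0.25, 0.25)))
  classify <- function(px, py, pz) {
    # returns material id: 0 air, 1 water, 2 plastic
    r2d <- sqrt(px^2 + py^2)
    out <- integer(length(px))
    inside_cyl <- r2d <= spec$cylinder_radius & pz >= 0 &
      pz <= spec$cylinder_height
    wall <- inside_cyl & r2d > spec$cylinder_radius - spec$shell_thickness
    slab <- inside_cyl & !wall & pz <= spec$base_slab_thickness
    water <- inside_cyl & !wall & !slab
    out[water] <- 1L
    out[wall | slab] <- 2L
    s <- spec$spheres
    for (i in seq_len(nrow(s))) {
      insph <- (px - s$x[i])^2 + (py - s$y[i])^2 + (pz - s$z[i])^2 <=
        s$radius[i]^2
      out[insph & water] <- 2L
    }
    out
  }
  px <- rep(xs, times = d[2]); py <- rep(ys, each = d[1])
  vox_diag <- sqrt(sum((sp / 2)^2))
  for (k in seq_len(d[3])) {
    pz <- rep(zs[k], length(px))
    cls <- classify(px, py, pz)
    # boundary voxels: centers near any material interface
    r2d <- sqrt(px^2 + py^2)
    db <- abs(r2d - spec$cylinder_radius)
    db <- pmin(db, abs(r2d - (spec$cylinder_radius - spec$shell_thickness)))
    db <- pmin(db, abs(pz - spec$base_slab_thickness),
               abs(pz - 0), abs(pz - spec$cylinder_height))
    s <- spec$spheres
    for (i in seq_len(nrow(s))) {
      ds <- abs(sqrt((px - s$x[i])^2 + (py - s$y[i])^2 +
                       (pz - s$z[i])^2) - s$radius[i])
      db <- pmin(db, ds)
    }
    bnd <- which(db <= vox_diag)
    wat <- as.numeric(cls == 1L); pla <- as.numeric(cls == 2L)
    if (length(bnd) > 0) {
      accw <- numeric(length(bnd)); accp <- numeric(length(bnd))
      for (si in seq_len(nrow(sub))) {
        qx <- px[bnd] + sub[si, 1] * sp[1]
        qy <- py[bnd] + sub[si, 2] * sp[2]
        qz <- pz[bnd] + sub[si, 3] * sp[3]
        c2 <- classify(qx, qy, qz)
        accw <- accw + (c2 == 1L)
        accp <- accp + (c2 == 2L)
      }
      wat[bnd] <- accw / nrow(sub)
      pla[bnd] <- accp / nrow(sub)
    }
    occ_water[, , k] <- wat
    occ_plastic[, , k] <- pla
  }
  list(frame = frame, water = occ_water, plastic = occ_plastic)
}

#' Render the digital phantom for one modality
#'
#' Partial-volume rendering (boundary voxels are 8x supersampled), Gaussian
#' blur at the modality PSF, and, when `noise_sigma > 0`, additive Gaussian
#' noise under the given seed.  Material assignment: spheres, base slab and
#' cylinder wall are plastic; the cylinder interior is water; everything
#' outside is air.  Noise-free renders are seed-independent.
#'
#' @param spec a [phantom_spec()].
#' @param model a [modality_model()].
#' @param seed RNG seed for the noise realization (required when
#'   `noise_sigma > 0`).
#' @return A [volume3d()] with the model's modality tag.
#' @export
render_phantom <- function(spec, model, seed = NULL) {
  validate_phantom_spec(spec)
  occ <- phantom_material_occupancy(spec, model)
  ints <- model$intensities
  img <- ints$air +
    occ$water * (ints$water - ints$air) +
    occ$plastic * (ints$plastic - ints$air)
  if (model$psf_fwhm > 0) {
    sigma_vox <- (model$psf_fwhm / 2.35482) / model$spacing
    img <- cpp_blur_gaussian(img, dim(img), sigma_vox)
  }
  if (model$noise_sigma > 0) {
    if (is.null(seed)) stop("`seed` is required when noise_sigma > 0")
    img <- img + with_seed(seed,
                           array(stats::rnorm(length(img), 0,
                                              model$noise_sigma), dim(img)))
  }
  volume3d(array(img, model$shape), model$spacing, occ$frame$origin,
           model$modality)
}

#' Modify a phantom target
#'
#' Returns a new spec differing from `spec` only in the named sphere;
#' changes violating the spec invariants (collision, out of bounds) are
#' errors.
#'
#' @param spec a [phantom_spec()].
#' @param change a [sphere_translation()] or [sphere_resize()].
#' @return The modified [phantom_spec()].
#' @export
modify_phantom <- function(spec, change) {
  s <- spec$spheres
  i <- match(change$id, s$id)
  if (is.na(i)) stop("no sphere with id ", change$id)
  if (inherits(change, "sphere_translation")) {
    s$x[i] <- s$x[i] + change$vector[1]
    s$y[i] <- s$y[i] + change$vector[2]
    s$z[i] <- s$z[i] + change$vector[3]
  } else if (inherits(change, "sphere_resize")) {
    s$radius[i] <- change$new_radius
  } else stop("unknown change type")
  out <- spec
  out$spheres <- s
  validate_phantom_spec(out)
  out
}

#' @rdname modify_phantom
#' @param id sphere id to modify.
#' @param vector length-3 mm translation.
#' @export
sphere_translation <- function(id, vector) {
  structure(list(id = id, vector = as.numeric(vector)),
            class = "sphere_translation")
}

#' @rdname modify_phantom
#' @param new_radius new sphere radius in mm (doubling the volume means
#'   `new_radius = radius * 2^(1/3)`).
#' @export
sphere_resize <- function(id, new_radius) {
  structure(list(id = id, new_radius = as.numeric(new_radius)),
            class = "sphere_resize")
}

#' Render a source/target scenario pair across modalities
#'
#' Renders the target from `spec` and the source from
#' `modify_phantom(spec, change)` for each modality model, and exports the
#' ground truth of the modification so downstream registration evaluations
#' have an absolute reference.
#'
#' @param spec a [phantom_spec()].
#' @param change a [sphere_translation()] or [sphere_resize()].
#' @param models list of [modality_model()]s.
#' @param seed base RNG seed; per-render seeds are derived
#'   deterministically.
#' @return A list of class `phantom_scenario`: `pairs` (one
#'   `list(modality, source, target)` per model) and `truth` (the change,
#'   with the displacement vector in mm for translations).
#' @export
scenario_pair <- function(spec, change, models, seed = 1) {
  modified <- modify_phantom(spec, change)
  pairs <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    list(modality = m$modality,
         source = render_phantom(modified, m, seed = seed + 2L * i),
         target = render_phantom(spec, m, seed = seed + 2L * i + 1L))
  })
  truth <- list(change = change,
                displacement_mm = if (inherits(change, "sphere_translation"))
                  sqrt(sum(change$vector^2)) else 0)
  structure(list(pairs = pairs, truth = truth), class = "phantom_scenario")
}
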