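fast_ct <- function(shape = c(64, 64, 16), spacing = c(3.5, 3.5, 8),
                    noise = 0) {
  modality_model("CT", list(water = 0, plastic = 120, air = -1000),
                 psf_fwhm = 0.7, noise_sigma = noise, shape = shape,
                 spacing = spacing)
}

test_that("phantom specs validate sphere placement and collisions", {
  expect_error(phantom_spec(spheres = data.frame(id = 1, x = 95, y = 0,
                                                 z = 60, radius = 10)),
               "exits the water cylinder")
  expect_error(phantom_spec(spheres = data.frame(id = 1:2, x = c(0, 4),
                                                 y = 0, z = 60,
                                                 radius = c(8, 8))),
               "intersect")
  expect_s3_class(phantom_spec(), "phantom_spec")
})

test_that("rendering is deterministic and noise is seed-controlled", {
  spec <- phantom_spec()
  m0 <- fast_ct()
  a <- render_phantom(spec, m0)
  b <- render_phantom(spec, m0)
  expect_identical(a$data, b$data)        # noise-free: seed-independent
  mn <- fast_ct(noise = 15)
  expect_error(render_phantom(spec, mn), "seed")
  n1 <- render_phantom(spec, mn, seed = 4)
  n2 <- render_phantom(spec, mn, seed = 4)
  n3 <- render_phantom(spec, mn, seed = 5)
  expect_identical(n1$data, n2$data)
  expect_false(identical(n1$data, n3$data))
})

test_that("partial-volume rendering reproduces analytic sphere volumes", {
  sp1 <- phantom_spec(spheres = data.frame(id = 1, x = 0, y = 0, z = 60,
                                           radius = 10))
  m <- modality_model("CT", list(water = 0, plastic = 100, air = 0),
                      psf_fwhm = 0, noise_sigma = 0, shape = c(60, 60, 40),
                      spacing = c(1, 1, 2))
  r <- render_phantom(sp1, m)
  occ <- r$data[, , regqa:::axis_coords(r, 3) > 40] / 100
  vol <- sum(occ) * prod(m$spacing)
  expect_lt(abs(vol / (4 / 3 * pi * 10^3) - 1), 0.02)
})

test_that("signal-void plastic shrinks the apparent phantom radius on MRI", {
  spec <- phantom_spec()
  ctm <- fast_ct(shape = c(128, 128, 16), spacing = c(1.8, 1.8, 8))
  mrm <- modality_model("MRI", list(water = 1000, plastic = 0, air = 0),
                        psf_fwhm = 0.8, noise_sigma = 0,
                        shape = c(128, 128, 16), spacing = c(1.8, 1.8, 8))
  ct <- render_phantom(spec, ctm)
  mri <- render_phantom(spec, mrm)
  apparent_radius <- function(v, inside, outside) {
    k <- round(dim(v$data)[3] / 2)
    j <- which.min(abs(regqa:::axis_coords(v, 2)))
    xs <- regqa:::axis_coords(v, 1)
    prof <- v$data[, j, k]
    half <- (inside + outside) / 2
    pos <- which(xs > 0)
    xs[pos[which(prof[pos] < half)[1]]]
  }
  rc <- apparent_radius(ct, 0, -1000)
  rm <- apparent_radius(mri, 1000, 0)
  expect_gte(rc - rm, ct$spacing[1])    # smaller by at least one voxel
})

test_that("PET renders cold spheres inside hot water", {
  spec <- phantom_spec()
  pm <- modality_model("PET", list(water = 1, plastic = 0, air = 0),
                       psf_fwhm = 6.5, noise_sigma = 0, shape = c(72, 72, 30),
                       spacing = c(3, 3, 4))
  pet <- render_phantom(spec, pm)
  s <- spec$spheres[5, ]   # the largest sphere rides above the slab
  ctr <- pet$data[physical_to_index(pet, c(s$x, s$y, s$z))[1],
                  physical_to_index(pet, c(s$x, s$y, s$z))[2],
                  physical_to_index(pet, c(s$x, s$y, s$z))[3]]
  water_ref <- pet$data[physical_to_index(pet, c(0, 40, 100))[1],
                        physical_to_index(pet, c(0, 40, 100))[2],
                        physical_to_index(pet, c(0, 40, 100))[3]]
  expect_lt(ctr, 0.1 * water_ref)
})

test_that("phantom modifications change exactly the named sphere", {
  spec <- phantom_spec()
  tr <- modify_phantom(spec, sphere_translation(2, c(8, 0, 0)))
  expect_equal(tr$spheres$x[2] - spec$spheres$x[2], 8)
  expect_equal(tr$spheres[-2, ], spec$spheres[-2, ])
  dbl <- modify_phantom(spec, sphere_resize(3, spec$spheres$radius[3] *
                                              2^(1 / 3)))
  expect_equal((dbl$spheres$radius[3] / spec$spheres$radius[3])^3, 2,
               tolerance = 1e-12)
  expect_error(modify_phantom(spec, sphere_translation(2, c(24, 48, 15))),
               "intersect|exits")
  expect_error(modify_phantom(spec, sphere_translation(99, c(1, 0, 0))),
               "no sphere")
})

test_that("translating a sphere conserves the water volume", {
  spec <- phantom_spec()
  m <- fast_ct(shape = c(80, 80, 24), spacing = c(2.8, 2.8, 5.5))
  before <- render_phantom(spec, m)
  after <- render_phantom(modify_phantom(spec, sphere_translation(2,
                                                                  c(8, 0, 0))),
                          m)
  water_frac <- function(v) sum(abs(v$data - 0) < 30) # near-water intensity
  expect_lt(abs(water_frac(after) / water_frac(before) - 1), 0.005)
})

test_that("scenario pairs export the ground-truth displacement", {
  spec <- phantom_spec()
  sc <- scenario_pair(spec, sphere_translation(2, c(8, 0, 0)),
                      list(fast_ct(noise = 5)), seed = 2)
  expect_equal(sc$truth$displacement_mm, 8)
  expect_equal(sc$pairs[[1]]$modality, "CT")
  # rendered sphere centroid moves by the commanded 8 mm
  src <- sc$pairs[[1]]$source; tgt <- sc$pairs[[1]]$target
  s <- spec$spheres[2, ]
  centroid <- function(v, cx, cy) {
    sel <- abs(v$data - 120) < 40
    pos <- regqa:::all_voxel_centers(v)[as.vector(sel), , drop = FALSE]
    near <- sqrt((pos[, 1] - cx)^2 + (pos[, 2] - cy)^2 +
                   (pos[, 3] - s$z)^2) < 2.5 * s$radius
    colMeans(pos[near, , drop = FALSE])
  }
  c_t <- centroid(tgt, s$x, s$y)
  c_s <- centroid(src, s$x + 8, s$y)
  expect_equal(c_s[1] - c_t[1], 8, tolerance = 0.5)
  expect_lt(abs(c_s[2] - c_t[2]), 1)
  # null change: images differ only by the noise realization
  sc0 <- scenario_pair(spec, sphere_translation(2, c(0, 0, 0)),
                       list(fast_ct(noise = 5)), seed = 2)
  d <- sc0$pairs[[1]]$source$data - sc0$pairs[[1]]$target$data
  expect_lt(max(abs(d)), 6 * 5 * sqrt(2))  # two noise draws, no shift
  # and a written scenario is re-readable with its truth
  dir <- file.path(tempdir(), "scen")
  paths <- export_scenario(sc, dir, "t8")
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::fromJSON(file.path(dir, "t8_truth.json"))
  expect_equal(truth$displacement_mm, 8)
})
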