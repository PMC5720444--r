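test_that("zero and constant coefficient fields behave like the identity and a translation", {
  frame <- deform_frame()
  t0 <- random_transform(frame, control_spacing = 20, max_coeff = 0, seed = 1)
  pts <- rbind(c(30, 40, 50), c(100, 120, 90), c(79.5, 33.3, 140))
  expect_equal(displacement_at(t0, pts), matrix(0, 3, 3))
  # partition of unity: constant coefficients give a constant displacement
  coef <- t0$coefficients
  coef[, , , 1] <- 4.25
  coef[, , , 3] <- -1.5
  tc <- bspline_transform(coef, t0$control_origin, t0$control_spacing)
  d <- displacement_at(tc, pts)
  expect_equal(d, matrix(rep(c(4.25, 0, -1.5), each = 3), 3, 3),
               tolerance = 1e-12)
})

test_that("a single coefficient reproduces the textbook tensor-product basis", {
  ct <- bspline_transform(array(0, c(8, 8, 8, 3)),
                          control_origin = c(0, 0, 0),
                          control_spacing = c(10, 12, 8))
  coef <- ct$coefficients
  coef[5, 4, 6, 1] <- 2.7   # 0-based control index (4, 3, 5)
  t1 <- bspline_transform(coef, ct$control_origin, ct$control_spacing)
  set.seed(11)
  for (r in 1:12) {
    p <- c(runif(1, 20, 50), runif(1, 24, 60), runif(1, 16, 40))
    tx <- p[1] / 10; ty <- p[2] / 12; tz <- p[3] / 8
    want <- 2.7 * b3(tx - 4) * b3(ty - 3) * b3(tz - 5)
    expect_lt(abs(displacement_at(t1, p)[1, 1] - want), 1e-12)
    expect_equal(displacement_at(t1, p)[1, 2:3], c(0, 0))
  }
})

test_that("scaling a transform scales its displacement field exactly linearly", {
  frame <- deform_frame()
  t1 <- random_transform(frame, control_spacing = 20, max_coeff = 5, seed = 2)
  th <- scale_transform(t1, 0.5)
  t0 <- scale_transform(t1, 0)
  set.seed(5)
  pts <- cbind(runif(100, 5, 150), runif(100, 5, 150), runif(100, 5, 170))
  d1 <- displacement_at(t1, pts)
  expect_lt(max(abs(displacement_at(th, pts) - 0.5 * d1)), 1e-9)
  expect_equal(displacement_at(t0, pts), matrix(0, 100, 3))
  expect_equal(scale_transform(t1, 1)$coefficients, t1$coefficients)
  expect_error(scale_transform(t1, -1), "nonnegative")
})

test_that("random transforms are reproducible and grow with amplitude", {
  frame <- deform_frame()
  a <- random_transform(frame, control_spacing = 20, max_coeff = 5, seed = 42)
  b <- random_transform(frame, control_spacing = 20, max_coeff = 5, seed = 42)
  expect_identical(a$coefficients, b$coefficients)
  # mean displacement magnitude increases monotonically with max_coeff
  amp <- c(1, 2, 4, 8, 16)
  mags <- vapply(seq_along(amp), function(i) {
    t <- random_transform(frame, control_spacing = 20, max_coeff = amp[i],
                          seed = 100 + i)
    true_de_dense(t, frame)["de_mm"]
  }, 0)
  expect_identical(order(mags), seq_along(amp))
  expect_error(random_transform(frame, control_spacing = -5, max_coeff = 1,
                                seed = 1),
               "positive")
})

test_that("displacement vanishes at the volume faces for boundary-zeroed transforms", {
  frame <- deform_frame()
  t1 <- random_transform(frame, control_spacing = 20, max_coeff = 6, seed = 8)
  ext <- physical_extent(frame)
  set.seed(6)
  face_pts <- rbind(
    cbind(ext["lo", 1], runif(10, 0, 150), runif(10, 0, 170)),
    cbind(ext["hi", 1], runif(10, 0, 150), runif(10, 0, 170)),
    cbind(runif(10, 0, 150), runif(10, 0, 150), ext["lo", 3]),
    cbind(runif(10, 0, 150), runif(10, 0, 150), ext["hi", 3]))
  expect_lt(max(abs(displacement_at(t1, face_pts))), 1e-12)
})

test_that("true displacement error matches the brute-force aggregate", {
  frame <- deform_frame()
  ps <- pointset(cbind(runif(10, 20, 140), runif(10, 20, 140),
                       runif(10, 20, 150)), frame = frame)
  expect_error(true_de(random_transform(frame, 20, 1, seed = 1),
                       pointset(matrix(numeric(0), 0, 3), integer(0),
                                frame)),
               "empty")
  tt <- translation_transform(c(3, 4, 0))
  expect_equal(unname(true_de(tt, ps)), c(5, 5))
  t1 <- random_transform(frame, control_spacing = 20, max_coeff = 6, seed = 3)
  mapped <- transform_points(t1, ps$points)
  want <- brute_de(ps$points, mapped)
  got <- true_de(t1, ps)
  expect_equal(unname(got["de_mm"]), unname(want["de"]), tolerance = 1e-9)
  expect_equal(unname(got["axial_de_mm"]), unname(want["axial"]),
               tolerance = 1e-9)
  # invariance under reordering of the point set
  ord <- sample(10)
  ps2 <- pointset(ps$points[ord, ], labels = 101:110, frame = frame)
  expect_equal(true_de(t1, ps2), got)
})

test_that("dense displacement error agrees with exhaustive per-voxel evaluation", {
  frame <- test_frame(c(12, 10, 6), spacing = c(8, 9, 20))
  big <- volume3d(array(0, c(60, 60, 30)), c(2, 2, 5))
  t1 <- random_transform(big, control_spacing = 20, max_coeff = 4, seed = 5)
  centers <- regqa:::all_voxel_centers(frame)
  want <- brute_de(centers, transform_points(t1, centers))
  got <- true_de_dense(t1, frame)
  expect_equal(unname(got["de_mm"]), unname(want["de"]), tolerance = 1e-9)
  expect_equal(unname(got["axial_de_mm"]), unname(want["axial"]),
               tolerance = 1e-9)
})

test_that("warping with the identity is bit-exact and translations shift the array", {
  frame <- deform_frame()
  v <- smooth_volume(frame)
  w <- warp_volume(v, random_transform(frame, 20, 0, seed = 1))
  expect_identical(w$data, v$data)
  # translation by exactly (1, -2, 1) voxels
  tt <- translation_transform(c(2, -4, 5))
  wt <- warp_volume(v, tt)
  expect_equal(wt$data[10:70, 10:70, 5:30],
               v$data[10:70 - 1, 10:70 + 2, 5:30 - 1], tolerance = 1e-12)
})

test_that("smooth warps approximately conserve interior intensity", {
  frame <- deform_frame()
  v <- smooth_volume(frame, seed = 2)
  t1 <- random_transform(frame, control_spacing = 20, max_coeff = 5, seed = 9)
  w <- warp_volume(v, t1)
  inner <- function(x) mean(x[11:70, 11:70, 6:31])
  expect_lt(abs(inner(w$data) / inner(v$data) - 1), 0.01)
})

test_that("composing a transform with its recovery yields the residual field", {
  frame <- deform_frame()
  ps <- pointset(cbind(runif(25, 30, 130), runif(25, 30, 130),
                       runif(25, 30, 140)), frame = frame)
  t0 <- random_transform(frame, control_spacing = 20, max_coeff = 5, seed = 4)
  # identity recovery reproduces the true displacement error
  r_id <- compose_residual(t0, translation_transform(c(0, 0, 0)), ps)
  want <- true_de(t0, ps)
  expect_equal(r_id$de_mm, unname(want["de_mm"]), tolerance = 1e-12)
  expect_equal(r_id$axial_de_mm, unname(want["axial_de_mm"]),
               tolerance = 1e-12)
  # exact inverse of a translation recovers perfectly
  r0 <- compose_residual(translation_transform(c(2, 0, 0)),
                         translation_transform(c(-2, 0, 0)), ps)
  expect_equal(r0$de_mm, 0)
  # random recovered transform matches brute-force composition
  t_rec <- random_transform(frame, control_spacing = 20, max_coeff = 2,
                            seed = 14)
  r <- compose_residual(t0, t_rec, ps)
  back <- transform_points(t_rec, transform_points(t0, ps$points))
  want2 <- brute_de(ps$points, back)
  expect_equal(r$de_mm, unname(want2["de"]), tolerance = 1e-9)
})

test_that("numerical inversion undoes the forward map to tolerance", {
  frame <- deform_frame()
  t1 <- random_transform(frame, control_spacing = 20, max_coeff = 4, seed = 6)
  set.seed(2)
  pts <- cbind(runif(50, 20, 140), runif(50, 20, 140), runif(50, 20, 150))
  round_trip <- transform_points(invert_transform(t1),
                                 transform_points(t1, pts))
  expect_lt(max(abs(round_trip - pts)), 0.02)
  expect_identical(invert_transform(invert_transform(t1)), t1)
})

test_that("transform JSON serialization round-trips exactly", {
  frame <- deform_frame()
  t1 <- random_transform(frame, control_spacing = 20, max_coeff = 5, seed = 7)
  path <- file.path(tempdir(), "t.json")
  write_transform(t1, path)
  r <- read_transform(path)
  expect_equal(r$coefficients, t1$coefficients, tolerance = 1e-15)
  expect_equal(r$control_origin, t1$control_origin)
  expect_equal(r$control_spacing, t1$control_spacing)
})
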