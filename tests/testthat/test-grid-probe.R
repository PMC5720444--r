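test_that("grid images plant the requested points reproducibly and separated", {
  frame <- test_frame(c(60, 60, 12), spacing = c(1, 1, 5))
  g1 <- make_grid_image(frame, 1, seed = 1)
  expect_equal(sum(g1$volume$data != 0), 1)
  g <- make_grid_image(frame, 150, seed = 9, min_separation = 3)
  expect_equal(nrow(g$truth$points), 150)
  expect_equal(sum(g$volume$data != 0), 150)
  dm <- regqa:::pairwise_dist(g$truth$points, g$truth$points)
  diag(dm) <- Inf
  expect_gte(min(dm), 3)
  g2 <- make_grid_image(frame, 150, seed = 9, min_separation = 3)
  expect_identical(g2$truth$points, g$truth$points)
  expect_error(make_grid_image(frame, 1e5, seed = 1, min_separation = 3,
                               max_attempts = 2e5),
               "infeasible")
})

test_that("forward splatting preserves mass and first moments", {
  frame <- test_frame(c(40, 40, 10), spacing = c(1, 1, 5))
  # deterministic interior grid (clear of the faces, no merging)
  idx <- as.matrix(expand.grid(seq(5, 35, by = 6), seq(5, 35, by = 6),
                               c(3, 6, 9)))[1:40, ]
  dat <- array(0, dim(frame$data)); dat[idx] <- 1
  g <- structure(list(volume = volume3d(dat, frame$spacing, frame$origin,
                                        "GRID"),
                      truth = pointset(index_to_physical(frame, idx),
                                       frame = frame)),
                 class = "grid_image")
  # identity: image and truth unchanged
  gid <- splat_forward(g, translation_transform(c(0, 0, 0)))
  expect_equal(gid$volume$data, g$volume$data)
  expect_equal(gid$truth$points, g$truth$points)
  # translation by exactly one voxel spacing shifts the array
  g1 <- splat_forward(g, translation_transform(c(1, 0, 0)))
  expect_equal(g1$volume$data[2:40, , ], g$volume$data[1:39, , ])
  # half-voxel translation splits each deposit 50/50 in x
  gh <- splat_forward(g, translation_transform(c(0.5, 0, 0)))
  nz <- which(gh$volume$data != 0)
  expect_true(all(abs(gh$volume$data[nz] - 0.5) < 1e-12))
  expect_equal(sum(gh$volume$data), 40, tolerance = 1e-9)
  # centroids of the splatted deposits equal the mapped positions
  det <- detect_points(gh$volume)
  ord <- order(det$points[, 1] + 1000 * det$points[, 2] +
                 1e6 * det$points[, 3])
  tru <- gh$truth$points
  ord2 <- order(tru[, 1] + 1000 * tru[, 2] + 1e6 * tru[, 3])
  expect_lt(max(abs(det$points[ord, ] - tru[ord2, ])), 1e-9)
})

test_that("points leaving the frame are excluded with a warning, never silently", {
  frame <- test_frame(c(20, 20, 6), spacing = c(1, 1, 5))
  # deterministic grid: 28 interior points plus 2 on the +x face
  idx <- rbind(as.matrix(expand.grid(seq(3, 15, by = 2), seq(3, 15, by = 2),
                                     3))[1:28, ],
               c(20, 5, 2), c(19, 17, 4))
  dat <- array(0, dim(frame$data)); dat[idx] <- 1
  g <- structure(list(volume = volume3d(dat, frame$spacing, frame$origin,
                                        "GRID"),
                      truth = pointset(index_to_physical(frame, idx),
                                       frame = frame)),
                 class = "grid_image")
  expect_warning(out <- splat_forward(g, translation_transform(c(2, 0, 0))),
                 "outside the frame")
  expect_equal(nrow(out$truth$points), 28)
  expect_equal(sum(out$volume$data), 28, tolerance = 1e-9)
  expect_error(suppressWarnings(
    splat_forward(g, translation_transform(c(15, 0, 0)))),
    "outside the frame")
})

test_that("detection returns one intensity-weighted centroid per component", {
  frame <- test_frame(c(30, 30, 8), spacing = c(1, 1, 4))
  dat <- array(0, dim(frame$data))
  dat[5, 5, 2] <- 1; dat[20, 7, 3] <- 1; dat[12, 25, 6] <- 1
  v <- volume3d(dat, frame$spacing, frame$origin, "GRID")
  det <- detect_points(v)
  expect_equal(nrow(det$points), 3)
  want <- index_to_physical(v, rbind(c(5, 5, 2), c(20, 7, 3), c(12, 25, 6)))
  ord <- order(det$points[, 3], det$points[, 2], det$points[, 1])
  ord2 <- order(want[, 3], want[, 2], want[, 1])
  expect_equal(det$points[ord, ], want[ord2, ], ignore_attr = TRUE)
  # two touching deposits merge into one component with mass two
  dat2 <- array(0, dim(frame$data))
  dat2[10, 10, 4] <- 1; dat2[11, 10, 4] <- 1
  det2 <- detect_points(volume3d(dat2, frame$spacing, frame$origin, "GRID"))
  expect_equal(nrow(det2$points), 1)
  expect_equal(attr(det2, "mass"), 2)
  expect_equal(det2$points[1, 1],
               mean(index_to_physical(v, rbind(c(10, 10, 4),
                                               c(11, 10, 4)))[, 1]))
  # nothing above threshold: empty set, not an error
  det3 <- detect_points(volume3d(array(0, c(4, 4, 4)), c(1, 1, 1)),
                        threshold = 0.5)
  expect_equal(nrow(det3$points), 0)
})

test_that("mutual nearest-neighbor matching pairs, rejects and accounts", {
  frame <- test_frame(c(50, 50, 10), spacing = c(1, 1, 5))
  set.seed(8)
  pts <- cbind(runif(20, 5, 44), runif(20, 5, 44), runif(20, 5, 40))
  ref <- pointset(pts, frame = frame)
  # identical sets: everything pairs with zero discards
  m0 <- match_points(ref, ref)
  expect_equal(nrow(m0$pairs), 20)
  expect_equal(m0$n_ambiguous_discarded, 0)
  # a uniform 1 mm shift pairs everything at 1 mm offsets
  det <- pointset(sweep(pts, 2, c(1, 0, 0), "+"), frame = frame)
  m1 <- match_points(ref, det, max_radius = 10)
  expect_equal(nrow(m1$pairs), 20)
  offs <- as.matrix(m1$pairs[, c("det_x", "det_y", "det_z")]) -
    as.matrix(m1$pairs[, c("ref_x", "ref_y", "ref_z")])
  expect_equal(offs, matrix(rep(c(1, 0, 0), each = 20), 20, 3),
               ignore_attr = TRUE)
  # two references 2 mm apart crossing near one detection: both discarded
  ref2 <- pointset(rbind(c(10, 10, 10), c(12, 10, 10)), frame = frame)
  det2 <- pointset(rbind(c(11, 10.2, 10)), frame = frame)
  m2 <- match_points(ref2, det2, max_radius = 10)
  expect_equal(nrow(m2$pairs), 0)
  expect_gte(m2$n_ambiguous_discarded, 1)
  # bookkeeping accounts for every input point
  expect_equal(nrow(m2$pairs) + m2$n_unmatched_truth +
                 m2$n_ambiguous_discarded, 2)
})

test_that("grid-probe DE equals the brute-force aggregate on matched pairs", {
  frame <- test_frame(c(80, 80, 12), spacing = c(1.5, 1.5, 5))
  g <- make_grid_image(frame, 80, seed = 5, min_separation = 7)
  # perfect recovery: the rendered original image
  r0 <- approximate_de(g, g$volume)
  expect_lt(r0$de_mm, 1e-6)
  expect_equal(r0$fraction_matched, 1)
  # constant residual (3, 4, 0): DE = axial = 5
  gd <- suppressWarnings(splat_forward(g, translation_transform(c(3, 4, 0))))
  r1 <- approximate_de(g, gd$volume)
  expect_equal(r1$de_mm, 5, tolerance = 0.01)
  expect_equal(r1$axial_de_mm, 5, tolerance = 0.01)
  # the report equals a brute-force evaluation over its own matched pairs
  mt <- r1$match$pairs
  want <- brute_de(as.matrix(mt[, c("ref_x", "ref_y", "ref_z")]),
                   as.matrix(mt[, c("det_x", "det_y", "det_z")]))
  expect_equal(r1$de_mm, unname(want["de"]), tolerance = 1e-9)
  expect_equal(r1$axial_de_mm, unname(want["axial"]), tolerance = 1e-9)
})

test_that("the coherent matcher tracks deformations beyond the probe spacing", {
  frame <- volume3d(array(0, c(160, 160, 24)), c(2, 2, 7.5))
  t0 <- random_transform(frame, control_spacing = 24, max_coeff = 22,
                         seed = 21)
  g <- make_grid_image(frame, 300, seed = 22, min_separation = 9)
  truth <- true_de(t0, g$truth)
  def <- suppressWarnings(splat_forward(g, t0))
  rep <- approximate_de(g, def$volume, method = "coherent")
  # per-point displacements approach the probe spacing in places; shared
  # centroids of merged deposits add bounded noise instead of biased loss
  expect_gt(true_de_dense(t0, frame)["max_mm"], 14)
  expect_lt(abs(rep$de_mm - truth["de_mm"]), 0.25)
  expect_gt(rep$fraction_matched, 0.95)
})

test_that("unreliable estimates are flagged and hopeless ones are errors", {
  frame <- test_frame(c(40, 40, 8), spacing = c(1, 1, 5))
  g <- make_grid_image(frame, 40, seed = 6, min_separation = 3)
  blank <- volume3d(array(0, dim(frame$data)), frame$spacing, frame$origin)
  expect_error(approximate_de(g, blank), "unreliable")
})

test_that("denser grids under strong deformation never fault less", {
  frame <- volume3d(array(0, c(140, 140, 24)), c(2, 2, 7.5))
  t0b <- random_transform(frame, control_spacing = 32, max_coeff = 10,
                          seed = 31)
  t0 <- scale_transform(t0b, 6.5 / true_de_dense(t0b, frame)["de_mm"])
  st <- accuracy_study(frame, list(t0), n_points_options = c(300, 1500),
                       seed = 77)
  expect_gte(st$n_faults[st$n_points == 1500],
             st$n_faults[st$n_points == 300])
  expect_gt(st$n_faults[st$n_points == 1500], 0)
})
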