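# Independent oracles and small fixture builders used across the suite.

# Centered cubic B-spline basis function (textbook piecewise definition).
b3 <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, (4 - 6 * ax^2 + 3 * ax^3) / 6,
         ifelse(ax < 2, (2 - ax)^3 / 6, 0))
}

# Brute-force RMS displacement-error aggregates from explicit per-point
# residual loops (no vectorized shortcuts shared with the implementation).
brute_de <- function(ref, det) {
  stopifnot(nrow(ref) == nrow(det))
  s3 <- 0; sax <- 0
  for (i in seq_len(nrow(ref))) {
    e <- as.numeric(det[i, ] - ref[i, ])
    s3 <- s3 + e[1]^2 + e[2]^2 + e[3]^2
    sax <- sax + e[1]^2 + e[2]^2
  }
  c(de = sqrt(s3 / nrow(ref)), axial = sqrt(sax / nrow(ref)))
}

# All-pairs symmetric mean surface distance oracle with loop-based surface
# extraction (6-neighbor complement test, faces count as background).
brute_msd <- function(a, b) {
  surf <- function(m) {
    d <- dim(m$data)
    pts <- NULL
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      if (!m$data[i, j, k]) next
      on_surface <- FALSE
      for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))) {
        q <- c(i, j, k) + off
        if (any(q < 1) || any(q > d) || !m$data[q[1], q[2], q[3]]) {
          on_surface <- TRUE
          break
        }
      }
      if (on_surface)
        pts <- rbind(pts, m$origin + (c(i, j, k) - 1) * m$spacing)
    }
    pts
  }
  sa <- surf(a); sb <- surf(b)
  dmean <- function(x, y) {
    tot <- 0
    for (i in seq_len(nrow(x))) {
      best <- Inf
      for (j in seq_len(nrow(y)))
        best <- min(best, sqrt(sum((x[i, ] - y[j, ])^2)))
      tot <- tot + best
    }
    tot / nrow(x)
  }
  (dmean(sa, sb) + dmean(sb, sa)) / 2
}

# Small geometric frame shared by many tests.
test_frame <- function(shape = c(40, 40, 20), spacing = c(2, 2, 4),
                       origin = c(0, 0, 0)) {
  volume3d(array(0, shape), spacing, origin)
}

# Frame large enough for a boundary-zeroed random transform at 16 mm
# control spacing.
deform_frame <- function() {
  volume3d(array(0, c(80, 80, 36)), spacing = c(2, 2, 5))
}

# Smooth synthetic intensity volume on a frame (separable cosine bumps).
smooth_volume <- function(frame, seed = 1) {
  d <- dim(frame$data)
  set.seed(seed)
  xs <- seq(0, 2 * pi, length.out = d[1])
  ys <- seq(0, 2 * pi, length.out = d[2])
  zs <- seq(0, 2 * pi, length.out = d[3])
  a <- runif(3, 0.5, 2)
  dat <- outer(outer(cos(a[1] * xs), sin(a[2] * ys)), cos(a[3] * zs)) +
    2 + array(0.01 * rnorm(prod(d)), d)
  volume3d(array(dat, d), frame$spacing, frame$origin)
}

# Random connected-ish binary mask (thresholded smooth field).
random_mask <- function(shape = c(10, 9, 6), spacing = c(1, 1, 1), seed = 1,
                        level = 0.5) {
  set.seed(seed)
  raw <- array(rnorm(prod(shape)), shape)
  sm <- regqa:::cpp_blur_gaussian(raw, as.integer(shape), c(1.2, 1.2, 1.2))
  binary_mask(array(sm > stats::quantile(sm, level), shape), spacing)
}

# Random convex polygon (points on a noisy ellipse, ordered by angle).
random_convex_polygon <- function(seed, cx = 0, cy = 0, rmax = 12) {
  set.seed(seed)
  n <- sample(3:9, 1)
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(1, 3, rmax)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# Deterministic-seed grid image with all points at least `margin` voxels
# from every face (for fixtures whose transforms must not eject points).
interior_grid <- function(frame, n, seed, margin = 3, min_separation = 4) {
  d <- dim(frame$data)
  set.seed(seed)
  acc <- matrix(0L, 0, 3)
  while (nrow(acc) < n) {
    idx <- c(sample(seq(margin + 1, d[1] - margin), 1),
             sample(seq(margin + 1, d[2] - margin), 1),
             sample(seq(margin + 1, d[3] - margin), 1))
    p <- frame$origin + (idx - 1) * frame$spacing
    if (nrow(acc) > 0) {
      prev <- sweep(sweep(acc, 2, 1), 2, frame$spacing, "*")
      prev <- sweep(prev, 2, frame$origin, "+")
      if (min(sqrt(rowSums(sweep(prev, 2, p, "-")^2))) < min_separation) next
    }
    acc <- rbind(acc, idx)
  }
  dat <- array(0, d); dat[acc] <- 1
  structure(list(volume = volume3d(dat, frame$spacing, frame$origin, "GRID"),
                 truth = pointset(index_to_physical(frame, acc),
                                  frame = frame)),
            class = "grid_image")
}
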