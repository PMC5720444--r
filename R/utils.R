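# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Physical voxel-center coordinates along one axis.
axis_coords <- function(v, axis) {
  v$origin[axis] + (seq_len(dim(v$data)[axis]) - 1) * v$spacing[axis]
}

# All voxel-center coordinates of a frame as an n x 3 matrix (use sparingly).
all_voxel_centers <- function(v) {
  d <- dim(v$data)
  cbind(rep(axis_coords(v, 1), times = d[2] * d[3]),
        rep(rep(axis_coords(v, 2), each = d[1]), times = d[3]),
        rep(axis_coords(v, 3), each = d[1] * d[2]))
}
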