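# Internal helpers shared across stages: seeded RNG scoping, voxel/physical
# coordinate conversions, sphere rasterization, point placement with minimum
# separation, and stderr logging.

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' Each generator call consumes its own RNG stream derived from
#' `(seed, stage)` so that stages are independently reproducible: re-running
#' one generator never perturbs another.
#'
#' @param seed Integer base seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% (.Machine$integer.max - 1))
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

# Physical position (micrometres) of a voxel centre; voxel i (1-based) sits
# at (i - 1) * voxel_size.  One convention, used everywhere.
index_to_um <- function(i, voxel) (i - 1) * voxel
um_to_index <- function(um, voxel) as.integer(round(um / voxel)) + 1L

# linear index into a [z, y, x] array
zyx_to_linear <- function(z, y, x, dim) {
  z + dim[1] * (y - 1L) + dim[1] * dim[2] * (x - 1L)
}

linear_to_zyx <- function(idx, dim) {
  arrayInd(idx, .dim = dim)
}

#' Voxel indices of a (possibly anisotropic) rasterized sphere
#'
#' @param dim Grid dimensions `(nz, ny, nx)`.
#' @param voxel Voxel size `(dz, dy, dx)` in um.
#' @param center Sphere centre in um `(z, y, x)`.
#' @param radius Radius in um.
#' @return Integer vector of linear indices into the `[z, y, x]` grid.
#' @keywords internal
rasterize_sphere <- function(dim, voxel, center, radius) {
  rng <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(1L, um_to_index(center[a] - radius, voxel[a]))
    hi <- min(dim[a], um_to_index(center[a] + radius, voxel[a]))
    if (lo > hi) return(integer(0))
    rng[[a]] <- lo:hi
  }
  d2 <- list()
  for (a in 1:3) d2[[a]] <- (index_to_um(rng[[a]], voxel[a]) - center[a])^2
  tot <- outer(outer(d2[[1]], d2[[2]], "+"), d2[[3]], "+")
  sel <- which(tot <= radius^2)
  if (length(sel) == 0L) return(integer(0))
  ld <- c(length(rng[[1]]), length(rng[[2]]), length(rng[[3]]))
  loc <- arrayInd(sel, .dim = ld)
  zyx_to_linear(rng[[1]][loc[, 1]], rng[[2]][loc[, 2]], rng[[3]][loc[, 3]], dim)
}

#' Random points with a minimum pairwise separation (sequential rejection)
#'
#' @param n Number of points.
#' @param lower,upper Numeric length-3 bounds (um) per axis `(z, y, x)`.
#' @param min_sep Minimum pairwise Euclidean separation (um).
#' @param max_tries Attempts per point before giving up.
#' @return An `n x 3` matrix of positions, or an error if the field is too
#'   crowded to accommodate `n` points.
#' @keywords internal
place_points_min_sep <- function(n, lower, upper, min_sep, max_tries = 2000L) {
  pts <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- lower + runif(3) * (upper - lower)
      if (i == 1L) { ok <- TRUE } else {
        prev <- pts[seq_len(i - 1L), , drop = FALSE]
        d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 + (prev[, 3] - p[3])^2
        ok <- all(d2 >= min_sep^2)
      }
      if (ok) { pts[i, ] <- p; break }
    }
    if (!ok) {
      stop("field too crowded: could not place ", n, " points with separation ",
           min_sep, " um after ", max_tries, " tries (placed ", i - 1L, ")")
    }
  }
  pts
}

# Bresenham raster of the segment (y0,x0)-(y1,x1): exactly one pixel per
# major-axis step, so the drawn line is 1 pixel wide and 8-connected
bresenham_line <- function(y0, x0, y1, x1) {
  dy <- abs(y1 - y0); dx <- abs(x1 - x0)
  sy <- sign(y1 - y0); sx <- sign(x1 - x0)
  n <- max(dy, dx) + 1L
  ys <- integer(n); xs <- integer(n)
  err <- dx - dy
  y <- y0; x <- x0
  for (i in seq_len(n)) {
    ys[i] <- y; xs[i] <- x
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  cbind(ys, xs)
}

# quantize noisy intensities to non-negative integer grey levels (camera
# counts); single truncation pass, upper clamp only when reachable
quantize_grey <- function(img, max_level = 65535) {
  img <- round(img)
  neg <- img < 0
  if (any(neg)) img[neg] <- 0
  if (max(img) > max_level) img[img > max_level] <- max_level
  img
}

# assemble named per-channel intensity vectors into a (c, z, y, x) array
stack_channels <- function(chan_data, dim3) {
  nc <- length(chan_data)
  data <- array(0, c(nc, dim3))
  for (j in seq_len(nc)) data[j, , , ] <- chan_data[[j]]
  data
}

#' Log a pipeline message to stderr
#' @param stage Short stage label.
#' @param ... Passed to [sprintf()].
#' @keywords internal
mq_log <- function(stage, ...) {
  message(sprintf("[microquant:%s] %s", stage, sprintf(...)))
}
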