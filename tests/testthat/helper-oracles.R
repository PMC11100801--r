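# Independent brute-force oracles and small fixture builders.  Oracles are
# deliberately written with different algorithms/data paths than the
# package implementations they check.

# --- pure-R connected components by BFS over an explicit neighbour list
oracle_cc_label <- function(arr, connectivity = 26L) {
  d <- dim(arr)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  ord <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- offs[ord > 0 & ord <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)], ]
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(arr)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        p <- ci + c(offs$dz[k], offs$dy[k], offs$dx[k])
        if (any(p < 1L) || any(p > d)) next
        li <- p[1] + d[1] * (p[2] - 1L) + d[1] * d[2] * (p[3] - 1L)
        if (arr[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# --- brute-force Sholl: bin every skeleton pixel by distance, then cluster
# in-band pixels with union-find over pairwise 8-adjacency
oracle_sholl <- function(skel_mat, pixel_size, center_um, radii) {
  pix <- which(skel_mat, arr.ind = TRUE)
  d <- sqrt(((pix[, 1] - 1) * pixel_size - center_um[1])^2 +
              ((pix[, 2] - 1) * pixel_size - center_um[2])^2)
  w <- pixel_size * sqrt(2)
  vapply(radii, function(r) {
    sel <- which(d >= r - w / 2 & d < r + w / 2)
    n <- length(sel)
    if (n == 0L) return(0L)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a < b &&
          abs(pix[sel[a], 1] - pix[sel[b], 1]) <= 1L &&
          abs(pix[sel[a], 2] - pix[sel[b], 2]) <= 1L) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
    length(unique(vapply(seq_len(n), find, integer(1))))
  }, integer(1))
}

# --- random-walk 1-pixel skeleton phantoms for oracle-equivalence tests
random_walk_skeleton <- function(seed, n_branches = 4, n_steps = 60,
                                 size_px = 200, pixel_size = 0.5) {
  set.seed(seed)
  img <- matrix(FALSE, size_px, size_px)
  c0 <- c(size_px / 2, size_px / 2)
  for (b in seq_len(n_branches)) {
    ang <- runif(1, 0, 2 * pi)
    pos <- c0
    img[round(pos[1]), round(pos[2])] <- TRUE
    for (s in seq_len(n_steps)) {
      ang <- ang + rnorm(1, 0, 0.25)
      nxt <- pos + c(sin(ang), cos(ang))
      nxt <- pmin(pmax(nxt, 2), size_px - 1)
      img[round(nxt[1]), round(nxt[2])] <- TRUE
      pos <- nxt
    }
  }
  list(img = img, center_um = (c0 - 1) * pixel_size, pixel_size = pixel_size)
}

# --- exhaustive colocalization matchers
oracle_coloc_overlap <- function(pre, post) {
  n_pre <- nrow(pre$table); n_post <- nrow(post$table)
  if (n_pre == 0L || n_post == 0L) return(0L)
  ov <- matrix(0L, n_pre, n_post)
  for (i in seq_len(n_pre)) for (j in seq_len(n_post)) {
    ov[i, j] <- length(intersect(pre$voxels[[i]], post$voxels[[j]]))
  }
  used_i <- logical(n_pre); used_j <- logical(n_post)
  count <- 0L
  repeat {
    ov[used_i, ] <- 0L; ov[, used_j] <- 0L
    if (max(ov) == 0L) break
    best <- which(ov == max(ov), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    used_i[best[1]] <- TRUE; used_j[best[2]] <- TRUE
    count <- count + 1L
  }
  count
}

oracle_coloc_centroid <- function(pre, post, r) {
  n_pre <- nrow(pre$table); n_post <- nrow(post$table)
  if (n_pre == 0L || n_post == 0L) return(0L)
  d <- matrix(Inf, n_pre, n_post)
  for (i in seq_len(n_pre)) for (j in seq_len(n_post)) {
    d[i, j] <- sqrt((pre$table$centroid_z_um[i] - post$table$centroid_z_um[j])^2 +
                      (pre$table$centroid_y_um[i] - post$table$centroid_y_um[j])^2 +
                      (pre$table$centroid_x_um[i] - post$table$centroid_x_um[j])^2)
  }
  count <- 0L
  repeat {
    if (min(d) > r) break
    best <- which(d == min(d), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    d[best[1], ] <- Inf; d[, best[2]] <- Inf
    count <- count + 1L
  }
  count
}

# --- brute-force histogram antimode search (fixed-width bins): find mode
# bins, then take the lowest bin between consecutive modes (middle of a
# flat valley on ties)
oracle_valley_cutoffs <- function(x, n_bins = 40) {
  h <- hist(x, breaks = n_bins, plot = FALSE)
  y <- h$counts
  high <- which(y >= 0.5 * max(y))
  grp <- cumsum(c(1, diff(high) > 1))
  modes <- vapply(split(high, grp), function(ix) ix[which.max(y[ix])], integer(1))
  stopifnot(length(modes) >= 3)
  cuts <- vapply(seq_len(length(modes) - 1L), function(k) {
    span <- modes[k]:modes[k + 1L]
    cand <- span[y[span] == min(y[span])]
    cand[ceiling(length(cand) / 2)]
  }, integer(1))
  sort(h$mids[cuts])[1:2]
}

# --- exact Euclidean distance-to-background (brute force, tiny masks)
oracle_exact_dt <- function(arr, voxel) {
  d <- dim(arr)
  fg <- which(arr); bg <- which(!arr)
  fgc <- arrayInd(fg, d); bgc <- arrayInd(bg, d)
  out <- array(0, d)
  for (k in seq_along(fg)) {
    dd <- sqrt(((fgc[k, 1] - bgc[, 1]) * voxel[1])^2 +
                 ((fgc[k, 2] - bgc[, 2]) * voxel[2])^2 +
                 ((fgc[k, 3] - bgc[, 3]) * voxel[3])^2)
    out[fg[k]] <- min(dd)
  }
  out
}

# --- small fixture configs
tiny_mg_config <- function(seed, n_cells = 2L, ...) {
  args <- list(seed = seed, n_cells = n_cells, field_shape = c(20L, 250L, 250L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}
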