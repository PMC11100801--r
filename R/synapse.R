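# Pre/postsynaptic puncta detection and colocalization counting: a synapse
# is one colocalized pre/post pair, matched one-to-one so a single large
# punctum cannot count several synapses.

#' Detect puncta in one channel
#'
#' Thresholded connected components restricted to a voxel-size window;
#' objects outside the window are rejected and counted in the log.
#'
#' @param v A [volume_image()].
#' @param channel Channel name or index.
#' @param threshold_method Passed to [threshold_channel()].
#' @param t Fixed threshold when `threshold_method = "fixed"`.
#' @param size_window `(min, max)` punctum size in voxels (min < max).
#' @param within Optional parent [binary_mask()].
#' @return A `puncta_set`: `table` (per-punctum centroid um, voxel count,
#'   mean intensity), `voxels` (per-punctum linear indices), `dim`,
#'   `voxel_size`, `n_rejected`.
#' @export
detect_puncta <- function(v, channel, threshold_method = "midpoint", t = NULL,
                          size_window = c(1, 60), within = NULL) {
  if (size_window[1] >= size_window[2]) stop("size_window must satisfy min < max")
  m <- threshold_channel(v, channel, method = threshold_method, t = t, within = within)
  lab <- .cc_label_cpp(as.vector(m$data), dim(m$data), 26L)
  arr <- get_channel(v, channel)
  n_raw <- max(lab)
  tab <- data.frame(
    punctum_id = integer(0), centroid_z_um = numeric(0),
    centroid_y_um = numeric(0), centroid_x_um = numeric(0),
    voxel_count = integer(0), mean_intensity = numeric(0)
  )
  vox <- list()
  n_rejected <- 0L
  if (n_raw > 0L) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    sizes <- tabulate(l, nbins = n_raw)
    keep <- which(sizes >= size_window[1] & sizes <= size_window[2])
    n_rejected <- n_raw - length(keep)
    if (n_rejected > 0L)
      mq_log("puncta", "%s: rejected %d object(s) outside size window [%d, %d]",
             as.character(channel), n_rejected, size_window[1], size_window[2])
    if (length(keep)) {
      sel <- l %in% keep
      idx <- idx[sel]; l <- l[sel]
      remap <- integer(n_raw); remap[keep] <- seq_along(keep)
      l <- remap[l]
      co <- linear_to_zyx(idx, dim(m$data))
      cnt <- tabulate(l, nbins = length(keep))
      cz <- rowsum(index_to_um(co[, 1], m$voxel_size[1]), l)[, 1] / cnt
      cy <- rowsum(index_to_um(co[, 2], m$voxel_size[2]), l)[, 1] / cnt
      cx <- rowsum(index_to_um(co[, 3], m$voxel_size[3]), l)[, 1] / cnt
      mi <- rowsum(arr[idx], l)[, 1] / cnt
      tab <- data.frame(
        punctum_id = seq_along(keep),
        centroid_z_um = cz, centroid_y_um = cy, centroid_x_um = cx,
        voxel_count = cnt, mean_intensity = mi
      )
      vox <- split(idx, l)
    }
  }
  structure(list(channel = as.character(channel), table = tab, voxels = vox,
                 dim = dim(m$data), voxel_size = m$voxel_size,
                 n_rejected = n_rejected),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> channel %s: %d puncta (%d rejected by size)\n",
              x$channel, nrow(x$table), x$n_rejected))
  invisible(x)
}

#' Count colocalized pre/post puncta pairs
#'
#' Criteria: `"overlap"` pairs puncta sharing at least one voxel;
#' `"centroid"` pairs puncta with centroid distance `<= r` um.  Matching
#' is one-to-one and greedy — best pair first (largest overlap / smallest
#' distance), distance ties broken by lower punctum index — so
#' `n_colocalized <= min(n_pre, n_post)` and the count is symmetric in the
#' two channels.
#'
#' @param pre,post [detect_puncta()] results on the same image frame.
#' @param criterion `"overlap"` or `"centroid"`.
#' @param r Centroid distance limit (um) for `criterion = "centroid"`.
#' @param area_um2 Analyzed field area for the density; default the full
#'   (y, x) field.
#' @return A `coloc_result`: `n_pre`, `n_post`, `n_colocalized`, `pairs`
#'   (matched id table), `density_per_100um2`, `criterion`.
#' @export
count_colocalized <- function(pre, post, criterion = c("overlap", "centroid"),
                              r = NULL, area_um2 = NULL) {
  criterion <- match.arg(criterion)
  if (!identical(pre$dim, post$dim)) stop("puncta sets are not on the same image frame")
  n_pre <- nrow(pre$table)
  n_post <- nrow(post$table)

  cand <- data.frame(pre = integer(0), post = integer(0), score = numeric(0))
  if (n_pre > 0L && n_post > 0L) {
    if (criterion == "overlap") {
      owner <- integer(prod(pre$dim))
      for (i in seq_len(n_pre)) owner[pre$voxels[[i]]] <- i
      rows <- list()
      for (j in seq_len(n_post)) {
        hits <- owner[post$voxels[[j]]]
        hits <- hits[hits > 0L]
        if (length(hits)) {
          tb <- table(hits)
          rows[[length(rows) + 1L]] <- data.frame(
            pre = as.integer(names(tb)), post = j, score = -as.integer(tb)
          )  # negative overlap: smaller score = better
        }
      }
      if (length(rows)) cand <- do.call(rbind, rows)
    } else {
      if (is.null(r) || r <= 0) stop("criterion 'centroid' needs a positive radius r")
      pz <- pre$table$centroid_z_um; py <- pre$table$centroid_y_um; px <- pre$table$centroid_x_um
      qz <- post$table$centroid_z_um; qy <- post$table$centroid_y_um; qx <- post$table$centroid_x_um
      d <- sqrt(outer(pz, qz, "-")^2 + outer(py, qy, "-")^2 + outer(px, qx, "-")^2)
      hit <- which(d <= r, arr.ind = TRUE)
      if (nrow(hit))
        cand <- data.frame(pre = hit[, 1], post = hit[, 2], score = d[hit])
    }
  }

  pairs <- data.frame(pre = integer(0), post = integer(0))
  if (nrow(cand)) {
    cand <- cand[order(cand$score, cand$pre, cand$post), , drop = FALSE]
    used_pre <- logical(n_pre)
    used_post <- logical(n_post)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$pre[k]; j <- cand$post[k]
      if (!used_pre[i] && !used_post[j]) {
        keep[k] <- TRUE
        used_pre[i] <- TRUE
        used_post[j] <- TRUE
      }
    }
    pairs <- cand[keep, c("pre", "post"), drop = FALSE]
  }
  if (is.null(area_um2))
    area_um2 <- prod((pre$dim[2:3] - 1L) * pre$voxel_size[2:3])
  structure(list(
    n_pre = n_pre, n_post = n_post, n_colocalized = nrow(pairs),
    pairs = pairs,
    density_per_100um2 = 100 * nrow(pairs) / area_um2,
    criterion = if (criterion == "overlap") "overlap" else sprintf("centroid:%g", r)
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d pre, %d post, %d colocalized (%s), %.3g per 100 um^2\n",
              x$n_pre, x$n_post, x$n_colocalized, x$criterion, x$density_per_100um2))
  invisible(x)
}
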