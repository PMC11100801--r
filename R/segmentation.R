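# Classical pixel classification -> object labeling -> size filtering ->
# per-object records.  This is a deliberate stand-in for a trained pixel
# classifier: the contract (binary pixel class, connected objects, size
# filter, counts) is preserved; the learned classifier is not reproduced.

#' Threshold one channel of a volume into a binary mask
#'
#' Methods: `"otsu"` (between-class-variance maximization on the intensity
#' histogram), `"fixed"` (user threshold `t`), and `"midpoint"` (halfway
#' between the median and the maximum intensity; robust for channels whose
#' foreground occupies a vanishing fraction of voxels, where Otsu can split
#' the background mode instead).  The mask is `intensity > threshold`.
#' With `within`, the threshold is computed from (and applied inside) the
#' given parent mask only, as when a marker channel is first masked by the
#' cell surface.
#'
#' @param v A [volume_image()].
#' @param channel Channel name or index.
#' @param method `"otsu"`, `"fixed"` or `"midpoint"`.
#' @param t Threshold for `method = "fixed"`.
#' @param within Optional [binary_mask()]; restrict both the threshold
#'   estimation and the output mask to its interior.
#' @return A [binary_mask()] with the chosen threshold in
#'   `attr(, "threshold")`.
#' @export
threshold_channel <- function(v, channel, method = c("otsu", "fixed", "midpoint"),
                              t = NULL, within = NULL) {
  method <- match.arg(method)
  arr <- get_channel(v, channel)
  if (!is.null(within)) {
    if (!identical(dim(within$data), dim(arr)))
      stop("'within' mask is not on the image lattice")
    vals <- arr[within$data]
    if (length(vals) == 0L) stop("'within' mask is empty")
  } else {
    vals <- as.vector(arr)
  }
  thr <- switch(method,
    fixed = {
      if (is.null(t) || !is.finite(t)) stop("method 'fixed' needs a finite threshold t")
      t
    },
    otsu = {
      rng <- range(vals)
      if (diff(rng) == 0) stop("Otsu threshold undefined on a constant image")
      EBImage::otsu(matrix(vals, ncol = 1L), range = rng, levels = 512L)
    },
    midpoint = {
      rng <- range(vals)
      if (diff(rng) == 0) stop("midpoint threshold undefined on a constant image")
      (median(vals) + max(vals)) / 2
    }
  )
  m <- arr > thr
  if (!is.null(within)) m <- m & within$data
  out <- binary_mask(m, v$voxel_size)
  attr(out, "threshold") <- as.numeric(thr)
  attr(out, "method") <- method
  out
}

#' Default minimum object size: a 2-um-radius sphere at the field's voxel size
#'
#' Excludes debris smaller than any soma.
#'
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param radius Radius of the smallest credible soma (um).
#' @return Integer voxel count.
#' @export
min_voxels_default <- function(voxel_size, radius = 2) {
  max(1L, as.integer(round((4 / 3) * pi * radius^3 / prod(voxel_size))))
}

#' Label connected objects in a binary mask
#'
#' 26-connectivity in 3D (8-connectivity for single-plane masks); objects
#' smaller than `min_voxels` are removed and counted in the log.  Labels
#' are renumbered 1..n in scan order, and all per-object properties are
#' recomputable exactly from the returned label grid.
#'
#' @param m A [binary_mask()].
#' @param min_voxels Minimum object size in voxels; default
#'   [min_voxels_default()] for the mask's voxel size.
#' @param connectivity 6, 18 or 26.
#' @return A `labeled_objects` list: `labels` (integer grid), `n`,
#'   `objects` (per-object table: voxel_count, volume_um3, centroid um,
#'   bounding box), `n_removed`.
#' @export
label_objects <- function(m, min_voxels = NULL, connectivity = 26L) {
  if (is.null(min_voxels)) min_voxels <- min_voxels_default(m$voxel_size)
  if (min_voxels < 1L) stop("min_voxels must be >= 1")
  lab <- .cc_label_cpp(as.vector(m$data), dim(m$data), as.integer(connectivity))
  n_raw <- max(lab)
  if (n_raw > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n_raw)
    keep <- which(sizes >= min_voxels)
    remap <- integer(n_raw)
    remap[keep] <- seq_along(keep)
    pos <- which(lab > 0L)
    lab[pos] <- remap[lab[pos]]
    n_removed <- n_raw - length(keep)
  } else {
    keep <- integer(0)
    n_removed <- 0L
  }
  n <- length(keep)
  if (n_removed > 0L)
    mq_log("segment", "removed %d object(s) below %d voxels", n_removed, min_voxels)

  objects <- data.frame(
    label = integer(0), voxel_count = integer(0), volume_um3 = numeric(0),
    centroid_z_um = numeric(0), centroid_y_um = numeric(0), centroid_x_um = numeric(0),
    z_min = integer(0), z_max = integer(0), y_min = integer(0), y_max = integer(0),
    x_min = integer(0), x_max = integer(0)
  )
  if (n > 0L) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    co <- linear_to_zyx(idx, dim(m$data))
    vvol <- prod(m$voxel_size)
    cnt <- tabulate(l, nbins = n)
    cz <- rowsum(index_to_um(co[, 1], m$voxel_size[1]), l)[, 1] / cnt
    cy <- rowsum(index_to_um(co[, 2], m$voxel_size[2]), l)[, 1] / cnt
    cx <- rowsum(index_to_um(co[, 3], m$voxel_size[3]), l)[, 1] / cnt
    bb <- function(f, a) as.integer(tapply(co[, a], l, f))
    objects <- data.frame(
      label = seq_len(n), voxel_count = cnt, volume_um3 = cnt * vvol,
      centroid_z_um = cz, centroid_y_um = cy, centroid_x_um = cx,
      z_min = bb(min, 1), z_max = bb(max, 1),
      y_min = bb(min, 2), y_max = bb(max, 2),
      x_min = bb(min, 3), x_max = bb(max, 3)
    )
  }
  structure(list(labels = lab, n = n, objects = objects,
                 voxel_size = m$voxel_size, n_removed = n_removed,
                 min_voxels = as.integer(min_voxels),
                 connectivity = as.integer(connectivity)),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %d object(s) (%d removed by size filter)\n",
              x$n, x$n_removed))
  invisible(x)
}

#' Count segmented cells
#'
#' @param lo A [label_objects()] result.
#' @return Integer object count.
#' @export
count_cells <- function(lo) lo$n

#' Extract per-cell objects with inscribed-core soma centroids
#'
#' One `cell_object` per retained label, with the mask cropped to its
#' padded bounding box.  The soma centroid is not the raw mask centroid
#' (which can fall outside a branched cell): it is the medoid of the
#' deepest-interior core, the connected set of voxels whose
#' distance-to-background is within 10% of the maximum, containing the
#' deepest voxel.
#'
#' @param lo A [label_objects()] result.
#' @param animal_id,image_id Metadata attached to each cell.
#' @param pad_um Bounding-box padding (um), default 2.
#' @return List of `cell_object`s (`mask` (cropped), `bbox`, `voxel_size`,
#'   `soma_centroid_um`, `volume_um3`, `voxel_count`, ids).
#' @export
extract_cells <- function(lo, animal_id = NA_character_, image_id = NA_character_,
                          pad_um = 2) {
  dims <- dim(lo$labels)
  pad <- pmax(1L, as.integer(ceiling(pad_um / lo$voxel_size)))
  out <- vector("list", lo$n)
  for (i in seq_len(lo$n)) {
    ob <- lo$objects[i, ]
    r <- list(
      z = c(max(1L, ob$z_min - pad[1]), min(dims[1], ob$z_max + pad[1])),
      y = c(max(1L, ob$y_min - pad[2]), min(dims[2], ob$y_max + pad[2])),
      x = c(max(1L, ob$x_min - pad[3]), min(dims[3], ob$x_max + pad[3]))
    )
    sub <- lo$labels[r$z[1]:r$z[2], r$y[1]:r$y[2], r$x[1]:r$x[2], drop = FALSE] == i
    dt <- .chamfer_dt_cpp(as.vector(sub), dim(sub), lo$voxel_size)
    dmax <- max(dt)
    core_cand <- array(dt >= 0.9 * dmax & sub, dim(sub))
    core_lab <- .cc_label_cpp(as.vector(core_cand), dim(sub), 26L)
    argmax <- which.max(dt)
    core <- which(core_lab == core_lab[argmax])
    co <- linear_to_zyx(core, dim(sub))
    ctr <- colMeans(co)
    medoid <- core[which.min((co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 +
                               (co[, 3] - ctr[3])^2)]
    mz <- linear_to_zyx(medoid, dim(sub))[1, ]
    soma <- c(
      index_to_um(r$z[1] + mz[1] - 1L, lo$voxel_size[1]),
      index_to_um(r$y[1] + mz[2] - 1L, lo$voxel_size[2]),
      index_to_um(r$x[1] + mz[3] - 1L, lo$voxel_size[3])
    )
    out[[i]] <- structure(list(
      cell_id = i, animal_id = animal_id, image_id = image_id,
      mask = sub, bbox = r, voxel_size = lo$voxel_size,
      soma_centroid_um = soma, soma_depth_um = dmax,
      voxel_count = ob$voxel_count,
      volume_um3 = ob$volume_um3
    ), class = "cell_object")
  }
  out
}

#' @export
print.cell_object <- function(x, ...) {
  cat(sprintf("<cell_object> id=%s, %d voxels (%.4g um^3), soma at (%.2f, %.2f, %.2f) um\n",
              x$cell_id, x$voxel_count, x$volume_um3,
              x$soma_centroid_um[1], x$soma_centroid_um[2], x$soma_centroid_um[3]))
  invisible(x)
}

# crop a full-lattice 3D array to a cell's bounding box
crop_to_cell <- function(arr, cell) {
  r <- cell$bbox
  arr[r$z[1]:r$z[2], r$y[1]:r$y[2], r$x[1]:r$x[2], drop = FALSE]
}

#' Segment microglia from the Iba1 channel (threshold -> label -> cells)
#'
#' @param v A [volume_image()].
#' @param channel Cell-body channel (default `"Iba1"`).
#' @param method Thresholding method (see [threshold_channel()]).
#' @param min_voxels Size filter, default [min_voxels_default()].
#' @param ... Passed to [extract_cells()].
#' @return List with `mask`, `labels` and `cells`.
#' @export
segment_microglia <- function(v, channel = "Iba1", method = "otsu",
                              min_voxels = NULL, ...) {
  m <- threshold_channel(v, channel, method = method)
  lo <- label_objects(m, min_voxels = min_voxels)
  list(mask = m, labels = lo, cells = extract_cells(lo, ...))
}
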