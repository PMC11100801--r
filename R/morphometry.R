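# 2D Sholl analysis: skeletonize the cell mask, then count connected runs
# of skeleton pixels on concentric 1-pixel-wide rings around the soma.

# shift a matrix by (dy, dx) with FALSE padding
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Skeletonize a 2D cell mask (Zhang-Suen thinning)
#'
#' Iterative two-subcycle thinning producing a 1-pixel-wide,
#' topology-preserving medial skeleton; the skeleton is always a subset of
#' the input mask.
#'
#' @param mask2d A [binary_mask()] with a single z-plane, or a logical
#'   matrix.
#' @return An object of the same kind as the input, containing the
#'   skeleton.
#' @export
skeletonize_cell <- function(mask2d) {
  was_mask <- inherits(mask2d, "binary_mask")
  if (was_mask) {
    if (dim(mask2d$data)[1] != 1L) stop("skeletonization is 2D: mask must have one z-plane")
    img <- matrix(mask2d$data[1, , ], dim(mask2d$data)[2], dim(mask2d$data)[3])
  } else {
    img <- mask2d
  }
  if (!any(img)) stop("cannot skeletonize an empty mask")

  neighbours <- function(m) {
    list(
      p2 = shift_mat(m, -1, 0), p3 = shift_mat(m, -1, 1), p4 = shift_mat(m, 0, 1),
      p5 = shift_mat(m, 1, 1), p6 = shift_mat(m, 1, 0), p7 = shift_mat(m, 1, -1),
      p8 = shift_mat(m, 0, -1), p9 = shift_mat(m, -1, -1)
    )
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- neighbours(img)
      b <- Reduce(`+`, nb)
      seqp <- with(nb, list(p2, p3, p4, p5, p6, p7, p8, p9, p2))
      a <- 0
      for (k in 1:8) a <- a + (!seqp[[k]] & seqp[[k + 1]])
      if (sub == 1) {
        c1 <- !(nb$p2 & nb$p4 & nb$p6)
        c2 <- !(nb$p4 & nb$p6 & nb$p8)
      } else {
        c1 <- !(nb$p2 & nb$p4 & nb$p8)
        c2 <- !(nb$p2 & nb$p6 & nb$p8)
      }
      del <- img & b >= 2 & b <= 6 & a == 1 & c1 & c2
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (was_mask) binary_mask(img, mask2d$voxel_size) else img
}

#' Sholl profile: ring-intersection counts around the soma
#'
#' For each radius `r` in an arithmetic sequence, the number of
#' intersections is the number of 8-connected runs of skeleton pixels on
#' the rasterized ring at `r`: pixels whose Euclidean distance from the
#' soma centre falls in `[r - w/2, r + w/2)` with the band thickness `w`
#' equal to the pixel diagonal.  That thickness is the thinnest band an
#' 8-connected skeleton path cannot jump across (a diagonal step advances
#' the radius by up to `p * sqrt(2)`), so every crossing process is
#' counted, and a thick crossing still counts once because its band pixels
#' form one connected run.  Rings that extend beyond the image border are
#' flagged in the `clipped` column, never silently truncated.
#'
#' @param skeleton A skeletonized [binary_mask()] (one z-plane) with square
#'   pixels, or a logical matrix plus `pixel_size`.
#' @param soma_center `(y, x)` in um; must lie inside the image.
#' @param ring_spacing Ring spacing in um (> 0), default 1.
#' @param max_radius Largest ring radius (um); default reaches the farthest
#'   skeleton pixel.
#' @param start_radius First ring radius (um); default `ring_spacing`.
#' @param pixel_size Pixel size when `skeleton` is a plain matrix.
#' @return A `sholl_profile` data frame: `radius_um`, `intersections`,
#'   `clipped`.
#' @export
sholl_profile <- function(skeleton, soma_center, ring_spacing = 1,
                          max_radius = NULL, start_radius = NULL,
                          pixel_size = NULL) {
  if (inherits(skeleton, "binary_mask")) {
    if (dim(skeleton$data)[1] != 1L) stop("Sholl analysis is 2D")
    if (abs(skeleton$voxel_size[2] - skeleton$voxel_size[3]) > 1e-9)
      stop("Sholl analysis requires square pixels")
    pixel_size <- skeleton$voxel_size[2]
    img <- matrix(skeleton$data[1, , ], dim(skeleton$data)[2], dim(skeleton$data)[3])
  } else {
    if (is.null(pixel_size)) stop("pixel_size required for a plain matrix")
    img <- skeleton
  }
  if (ring_spacing <= 0) stop("ring_spacing must be > 0")
  ext <- (dim(img) - 1L) * pixel_size
  if (any(soma_center < 0) || any(soma_center > ext))
    stop("soma_center lies outside the image")

  pix <- which(img, arr.ind = TRUE)
  d <- sqrt((index_to_um(pix[, 1], pixel_size) - soma_center[1])^2 +
              (index_to_um(pix[, 2], pixel_size) - soma_center[2])^2)
  if (is.null(start_radius)) start_radius <- ring_spacing
  if (is.null(max_radius)) {
    max_radius <- if (length(d)) max(d) + ring_spacing else start_radius
  }
  radii <- seq(start_radius, max_radius, by = ring_spacing)
  if (length(radii) == 0L) stop("no rings between start_radius and max_radius")
  w <- pixel_size * sqrt(2)
  if (ring_spacing < w)
    warning("ring_spacing below the band thickness (pixel diagonal): rings overlap")
  border_dist <- min(soma_center[1], soma_center[2],
                     ext[1] - soma_center[1], ext[2] - soma_center[2])

  inter <- integer(length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    on_ring <- d >= r - w / 2 & d < r + w / 2
    if (!any(on_ring)) next
    ring_img <- matrix(FALSE, nrow(img), ncol(img))
    ring_img[pix[on_ring, , drop = FALSE]] <- TRUE
    lab <- .cc_label_cpp(as.vector(array(ring_img, c(1L, dim(ring_img)))),
                         c(1L, dim(ring_img)), 26L)
    inter[k] <- max(lab)
  }
  out <- data.frame(radius_um = radii, intersections = inter,
                    clipped = radii > border_dist)
  class(out) <- c("sholl_profile", "data.frame")
  attr(out, "ring_spacing") <- ring_spacing
  attr(out, "pixel_size") <- pixel_size
  out
}

#' Sholl profile of a segmented cell
#'
#' Projects the cell mask (maximum over z), skeletonizes it, and runs
#' [sholl_profile()] with rings starting one spacing beyond the estimated
#' soma radius (the cell's deepest interior distance).
#'
#' @param cell A `cell_object` from [extract_cells()].
#' @param ring_spacing Ring spacing (um).
#' @param ... Passed to [sholl_profile()].
#' @return A `sholl_profile` with a `cell_id` attribute.
#' @export
sholl_for_cell <- function(cell, ring_spacing = 1, ...) {
  mip <- apply(cell$mask, c(2, 3), any)
  skel <- skeletonize_cell(binary_mask(mip, cell$voxel_size))
  center <- cell$soma_centroid_um[2:3] -
    c(index_to_um(cell$bbox$y[1], cell$voxel_size[2]),
      index_to_um(cell$bbox$x[1], cell$voxel_size[3]))
  start <- max(cell$soma_depth_um, ring_spacing) + ring_spacing
  prof <- sholl_profile(skel, center, ring_spacing = ring_spacing,
                        start_radius = start, ...)
  attr(prof, "cell_id") <- cell$cell_id
  prof
}

#' Volume of a binary mask in um^3
#'
#' True-voxel count times the physical voxel volume.
#'
#' @param mask A [binary_mask()].
#' @return Volume in um^3.
#' @export
cell_volume <- function(mask) mask_volume(mask)
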