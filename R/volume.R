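# The shared image data model: multi-channel intensity volumes and binary
# masks on a common (z, y, x) lattice with physical voxel sizes.

#' Construct a multi-channel intensity volume
#'
#' `VolumeImage` is the common substrate of every imaging stage: a numeric
#' grid indexed `(channel, z, y, x)` plus the physical voxel size.  A 2D
#' image is a volume with a single z-plane.
#'
#' @param data Numeric 4D array indexed `(channel, z, y, x)`; intensities
#'   must be finite and non-negative.
#' @param voxel_size Numeric length-3, `(dz, dy, dx)` in micrometres,
#'   strictly positive.
#' @param channel_names Character vector of unique channel labels, one per
#'   entry of the channel axis.
#' @return A `volume_image` object.
#' @export
volume_image <- function(data, voxel_size, channel_names) {
  if (length(dim(data)) != 4L) stop("data must be a 4D (channel, z, y, x) array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive values (dz, dy, dx)")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[1] || anyDuplicated(channel_names))
    stop("channel_names must be unique and match the channel axis length")
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and non-negative")
  new_volume_image(data, voxel_size, channel_names)
}

# fast internal constructor for data already valid by construction
new_volume_image <- function(data, voxel_size, channel_names) {
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         channel_names = as.character(channel_names)),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_image> %d channel(s) [%s], grid %d x %d x %d (z,y,x), voxel %.3g x %.3g x %.3g um\n",
    d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

grid_dim <- function(v) dim(v$data)[2:4]

channel_index <- function(v, channel) {
  if (is.character(channel)) {
    ic <- match(channel, v$channel_names)
    if (is.na(ic)) stop("unknown channel: ", channel)
  } else {
    ic <- as.integer(channel)
    if (ic < 1L || ic > dim(v$data)[1]) stop("channel index out of range")
  }
  ic
}

#' Extract one channel of a volume as a 3D `(z, y, x)` array
#'
#' @param v A [volume_image()].
#' @param channel Channel name or index.
#' @return Numeric 3D array.
#' @export
get_channel <- function(v, channel) {
  ic <- channel_index(v, channel)
  arr <- v$data[ic, , , , drop = FALSE]
  dim(arr) <- dim(v$data)[2:4]
  arr
}

#' Maximum-intensity projection of one channel
#'
#' Collapses the z-axis by the per-(y, x) maximum, as used for all 20x
#' counting/intensity analyses.  Idempotent on single-plane input.
#'
#' @param v A [volume_image()].
#' @param channel Channel name or index.
#' @return A single-channel `volume_image` with one z-plane.
#' @export
max_intensity_projection <- function(v, channel) {
  ic <- channel_index(v, channel)
  arr <- get_channel(v, ic)
  nz <- dim(arr)[1]
  if (nz == 1L) {
    mip <- arr[1, , ]
  } else {
    m <- matrix(arr, nrow = nz)
    mip <- matrix(do.call(pmax, lapply(seq_len(nz), function(i) m[i, ])),
                  dim(arr)[2], dim(arr)[3])
  }
  out <- array(mip, c(1L, 1L, dim(arr)[2], dim(arr)[3]))
  volume_image(out, v$voxel_size, v$channel_names[ic])
}

#' Construct a binary mask on an image lattice
#'
#' @param data Logical 3D `(z, y, x)` array, or a 2D matrix (treated as one
#'   z-plane).
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, voxel_size) {
  if (is.matrix(data)) {
    data <- array(data, c(1L, nrow(data), ncol(data)))
  }
  if (length(dim(data)) != 3L) stop("mask data must be a 3D (z, y, x) array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask must not contain NA")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive values")
  structure(list(data = data, voxel_size = voxel_size), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> grid %d x %d x %d (z,y,x), %d true voxels, %.4g um^3\n",
              d[1], d[2], d[3], sum(x$data), mask_volume(x)))
  invisible(x)
}

#' Physical volume of a binary mask
#'
#' Volume is the true-voxel count times the voxel volume; no mesh smoothing
#' is applied.
#'
#' @param m A [binary_mask()].
#' @return Volume in um^3.
#' @export
mask_volume <- function(m) {
  sum(m$data) * prod(m$voxel_size)
}

#' Number of true voxels in a mask
#' @param m A [binary_mask()].
#' @return Integer voxel count.
#' @export
mask_voxel_count <- function(m) sum(m$data)

same_lattice <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

#' Restrict one mask to the interior of another
#'
#' Voxelwise conjunction, the primitive behind every nested-channel
#' measurement (CD68 within the cell, VGlut2 within the lysosome).
#'
#' @param outer,inner [binary_mask()] objects on the same lattice.
#' @return A `binary_mask` equal to `outer AND inner`.
#' @export
mask_within <- function(outer, inner) {
  if (!same_lattice(outer, inner)) stop("masks are not on the same lattice")
  binary_mask(outer$data & inner$data, outer$voxel_size)
}
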