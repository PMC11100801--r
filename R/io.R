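# TIFF volume reading/writing with a JSON metadata sidecar, and result
# tables serialized as CSV with a JSON run manifest.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multi-channel volume to a multi-page TIFF
#'
#' Pages are written channel-major (all z-planes of channel 1, then channel
#' 2, ...) as 16-bit integers; intensities must already be integer grey
#' levels in `[0, 65535]`, which makes the write/read round trip bit-exact.
#' Channel names, grid shape and voxel size go to a JSON sidecar
#' (`<path>.json`).
#'
#' @param v A [volume_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  d <- dim(v$data)
  if (any(v$data != round(v$data)) || any(v$data > 65535))
    stop("write_volume stores 16-bit integer grey levels; intensities must be integers in [0, 65535]")
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ic in seq_len(d[1])) {
    for (iz in seq_len(d[2])) {
      pages[[k]] <- matrix(v$data[ic, iz, , ] / 65535, d[3], d[4])
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    channel_names = v$channel_names,
    shape_zyx = d[2:4],
    voxel_size_um = v$voxel_size
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume from TIFF (+ optional JSON sidecar)
#'
#' Axes are normalized to `(channel, z, y, x)`; a plain 2D TIFF becomes a
#' one-channel, one-plane volume.  The voxel size comes from the sidecar or
#' from `voxel_size_override`; if both are present the override wins with a
#' warning, and if neither is available reading fails rather than silently
#' assuming a default.
#'
#' @param path TIFF path.
#' @param voxel_size_override Optional `(dz, dy, dx)` in micrometres.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, voxel_size_override = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (!is.null(meta)) {
    shape <- as.integer(meta$shape_zyx)
    channels <- as.character(meta$channel_names)
    nc <- length(channels)
    if (nc * shape[1] != length(pages))
      stop("sidecar shape does not match TIFF page count")
  } else {
    shape <- c(length(pages), nrow(pages[[1]]), ncol(pages[[1]]))
    channels <- "channel1"
    nc <- 1L
  }
  voxel <- NULL
  if (!is.null(meta) && !is.null(meta$voxel_size_um)) voxel <- as.numeric(meta$voxel_size_um)
  if (!is.null(voxel_size_override)) {
    if (!is.null(voxel) && !isTRUE(all.equal(voxel, as.numeric(voxel_size_override)))) {
      warning("voxel size override (", paste(voxel_size_override, collapse = "x"),
              ") conflicts with sidecar metadata (", paste(voxel, collapse = "x"),
              "); using the override")
    }
    voxel <- as.numeric(voxel_size_override)
  }
  if (is.null(voxel))
    stop("no voxel size in metadata and no voxel_size_override supplied")
  data <- array(0, c(nc, shape))
  k <- 1L
  for (ic in seq_len(nc)) {
    for (iz in seq_len(shape[1])) {
      pg <- pages[[k]]
      if (is.array(pg) && length(dim(pg)) == 3L) pg <- pg[, , 1]  # greyscale written, be liberal
      data[ic, iz, , ] <- round(pg * 65535)
      k <- k + 1L
    }
  }
  volume_image(data, voxel, channels)
}

#' Write a result table as CSV with a JSON run manifest
#'
#' Every stage output is a flat table keyed by identifier columns; the
#' manifest records the configuration hash, seed and package version so any
#' table can be traced back to the run that produced it.
#'
#' @param df A data frame.
#' @param path Output CSV path.
#' @param config Optional configuration object to hash into the manifest.
#' @param seed Optional seed to record.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, config = NULL, seed = NULL, extra = list()) {
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- c(list(
    rows = nrow(df),
    columns = names(df),
    config_hash = if (is.null(config)) NA_character_ else rlang::hash(config),
    seed = if (is.null(seed)) NA_integer_ else seed,
    package_version = as.character(utils::packageVersion("microquant"))
  ), extra)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
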