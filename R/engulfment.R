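# Nested-mask engulfment volumetrics at voxel level: lysosomal (CD68)
# content within the cell, synaptic (VGlut2) material within the lysosome,
# normalized to cell volume.  Volumes are voxel counts times voxel volume;
# no surface meshing or smoothing.

#' Phagocytic capacity of one cell
#'
#' `100 * volume(CD68 within the cell mask) / volume(cell mask)` — the
#' fraction of the cell occupied by lysosomes, in percent.
#'
#' @param cell A `cell_object` from [extract_cells()].
#' @param cd68 A [binary_mask()] of the lysosomal channel on the full
#'   image lattice (or already cropped to the cell's bounding box).
#' @return Percentage in `[0, 100]`.
#' @export
phagocytic_capacity <- function(cell, cd68) {
  if (cell$voxel_count == 0L) stop("empty cell mask")
  sub <- cd68_crop(cell, cd68)
  100 * sum(cell$mask & sub) / cell$voxel_count
}

cd68_crop <- function(cell, m) {
  arr <- if (inherits(m, "binary_mask")) m$data else m
  if (identical(dim(arr), dim(cell$mask))) return(arr)
  crop_to_cell(arr, cell)
}

#' Per-cell nested engulfment record
#'
#' The nesting chain is enforced by construction: the lysosome mask is
#' `cell AND CD68`, the engulfed mask is `lysosome AND VGlut2`, so
#' `engulfed <= lysosome <= cell` holds for every input.
#'
#' @param cell A `cell_object`.
#' @param cd68,vglut2 [binary_mask()]s on the full image lattice.
#' @return One-row data frame: `cell_id`, `cell_volume_um3`,
#'   `lysosome_volume_um3`, `engulfed_synaptic_volume_um3`,
#'   `phagocytic_capacity_pct`, `engulfed_norm`, plus raw voxel counts.
#' @export
engulfed_synaptic_volume <- function(cell, cd68, vglut2) {
  if (cell$voxel_count == 0L) stop("empty cell mask")
  cd <- cd68_crop(cell, cd68)
  vg <- cd68_crop(cell, vglut2)
  lyso <- cell$mask & cd
  eng <- lyso & vg
  vvol <- prod(cell$voxel_size)
  n_ly <- sum(lyso)
  n_en <- sum(eng)
  data.frame(
    cell_id = cell$cell_id,
    animal_id = cell$animal_id,
    image_id = cell$image_id,
    cell_voxels = cell$voxel_count,
    cell_volume_um3 = cell$voxel_count * vvol,
    lysosome_voxels = n_ly,
    lysosome_volume_um3 = n_ly * vvol,
    engulfed_voxels = n_en,
    engulfed_synaptic_volume_um3 = n_en * vvol,
    phagocytic_capacity_pct = 100 * n_ly / cell$voxel_count,
    engulfed_norm = n_en / cell$voxel_count
  )
}

#' Measure engulfment for every cell in a volume
#'
#' Full pipeline: threshold CD68 inside the union cell mask and VGlut2
#' inside the lysosome mask (midpoint thresholds by default: both channels
#' are sparse), then emit one [engulfed_synaptic_volume()] record per cell.
#'
#' @param v A [volume_image()] with Iba1, CD68 and VGlut2 channels.
#' @param seg A [segment_microglia()] result for `v` (segmented Iba1).
#' @param cd68_channel,vglut2_channel Channel names.
#' @param method Threshold method for the marker channels.
#' @return Data frame of per-cell engulfment records.
#' @export
measure_engulfment <- function(v, seg, cd68_channel = "CD68",
                               vglut2_channel = "VGlut2",
                               method = "midpoint") {
  cd68 <- threshold_channel(v, cd68_channel, method = method)
  vglut2 <- threshold_channel(v, vglut2_channel, method = method)
  rows <- lapply(seg$cells, engulfed_synaptic_volume, cd68 = cd68, vglut2 = vglut2)
  do.call(rbind, rows)
}
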