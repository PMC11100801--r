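# Helpers linking measured objects back to generator ground truth for
# recovery studies.

#' Match segmented cells to ground-truth cells
#'
#' Each measured cell is assigned the generating cell whose truth label
#' occupies the majority of its mask voxels (0 = unmatched).
#'
#' @param cells List of `cell_object`s from [extract_cells()].
#' @param truth An `mg_truth` from [generate_microglia_volume()].
#' @return Integer vector of truth cell ids, one per measured cell.
#' @export
match_cells_to_truth <- function(cells, truth) {
  vapply(cells, function(cell) {
    sub <- crop_to_cell(truth$label_grid, cell)
    l <- sub[cell$mask]
    l <- l[l > 0L]
    if (length(l) == 0L) return(0L)
    as.integer(names(which.max(table(l))))
  }, integer(1))
}

#' True per-cell phagocytic capacity from generator truth
#'
#' @param truth An `mg_truth`.
#' @return Numeric vector of percentages, one per generated cell.
#' @export
truth_capacity <- function(truth) {
  100 * truth$cells$lysosome_voxels / truth$cells$voxel_count
}
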