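# Single-cell RNA-FISH scoring: nucleus segmentation, puncta-to-cell
# assignment by centroid, glutamatergic/GABAergic typing, size-adjusted
# Fos activity calls, and DAPI-volume-normalized target density with
# animal-level averaging.

#' Segment nuclei from the DAPI channel
#'
#' Threshold + connected components + size filter, one labeled nucleus per
#' cell.
#'
#' @param v A [volume_image()].
#' @param channel DAPI channel name.
#' @param method Threshold method.
#' @param min_voxels Size filter; default a 2-um-radius sphere.
#' @return A [label_objects()] result.
#' @export
segment_nuclei <- function(v, channel = "DAPI", method = "otsu", min_voxels = NULL) {
  m <- threshold_channel(v, channel, method = method)
  label_objects(m, min_voxels = min_voxels)
}

#' Assign detected puncta to nuclei by centroid containment
#'
#' A punctum belongs to the nucleus whose mask contains its centroid;
#' puncta whose centroids fall in background are tallied as unassigned
#' (assigned + unassigned = detected, always).
#'
#' @param puncta A [detect_puncta()] result.
#' @param nuclei A [label_objects()] result (nucleus labels).
#' @return List: `counts` (integer per nucleus 1..n), `n_unassigned`.
#' @export
assign_puncta <- function(puncta, nuclei) {
  n <- nuclei$n
  counts <- integer(n)
  n_unassigned <- 0L
  if (nrow(puncta$table) > 0L) {
    dims <- dim(nuclei$labels)
    iz <- pmin(pmax(um_to_index(puncta$table$centroid_z_um, nuclei$voxel_size[1]), 1L), dims[1])
    iy <- pmin(pmax(um_to_index(puncta$table$centroid_y_um, nuclei$voxel_size[2]), 1L), dims[2])
    ix <- pmin(pmax(um_to_index(puncta$table$centroid_x_um, nuclei$voxel_size[3]), 1L), dims[3])
    lab <- nuclei$labels[cbind(iz, iy, ix)]
    n_unassigned <- sum(lab == 0L)
    if (any(lab > 0L)) counts <- tabulate(lab[lab > 0L], nbins = n)
  }
  list(counts = counts, n_unassigned = n_unassigned)
}

#' Call a cell glutamatergic or GABAergic from marker puncta counts
#'
#' Glutamatergic when VGlut1 exceeds Gad2 by at least `min_margin` puncta,
#' GABAergic for the reverse, ambiguous otherwise (ambiguous cells are
#' excluded from type averages but kept in the table).
#'
#' @param vglut1_count,gad2_count Per-cell puncta counts (vectorized).
#' @param min_margin Required margin in puncta (>= 1), default 3.
#' @return Character vector in
#'   `{"glutamatergic", "GABAergic", "ambiguous"}`.
#' @export
call_cell_type <- function(vglut1_count, gad2_count, min_margin = 3L) {
  if (min_margin < 1L) stop("min_margin must be >= 1")
  ifelse(vglut1_count >= gad2_count + min_margin, "glutamatergic",
         ifelse(gad2_count >= vglut1_count + min_margin, "GABAergic", "ambiguous"))
}

#' Call Fos activity state with a size-adjusted threshold
#'
#' A cell is Fos+ when its Fos puncta count strictly exceeds the base
#' threshold (6 puncta) scaled by its nucleus volume relative to the
#' population median: `fos_count > base_threshold * dapi_volume /
#' median_volume`.  A count of exactly 6 at the median volume is Fos-.
#'
#' @param fos_count Per-cell Fos puncta counts (vectorized).
#' @param dapi_volume Per-cell nucleus volumes (um^3).
#' @param median_volume Population median nucleus volume (> 0).
#' @param base_threshold Base puncta threshold, default 6.
#' @return Character vector in `{"Fos+", "Fos-"}`.
#' @export
call_fos_state <- function(fos_count, dapi_volume, median_volume, base_threshold = 6) {
  if (median_volume <= 0) stop("median_volume must be > 0")
  ifelse(fos_count > base_threshold * dapi_volume / median_volume, "Fos+", "Fos-")
}

#' Quantify a FISH field into per-cell records
#'
#' Segments nuclei from DAPI, detects puncta per marker channel (midpoint
#' threshold: puncta occupy a vanishing voxel fraction), assigns them to
#' nuclei by centroid, then calls cell type, Fos state, and the
#' DAPI-normalized target density.
#'
#' @param v A [volume_image()] with a DAPI channel plus puncta channels.
#' @param animal_id Animal identifier for the records.
#' @param type_channels Named pair of typing channels
#'   (`vglut1`, `gad2`).
#' @param fos_channel,target_channel Activity and target channel names;
#'   either may be absent from the volume (columns are then omitted).
#' @param min_margin Typing margin (puncta).
#' @param size_window Punctum size window in voxels.
#' @return Data frame of per-nucleus records (`fish_records`): counts per
#'   channel, `dapi_volume_um3`, `cell_type`, `fos_state`,
#'   `target_density_per_um3`.
#' @export
quantify_fish <- function(v, animal_id = NA_character_,
                          type_channels = c(vglut1 = "VGlut1", gad2 = "Gad2"),
                          fos_channel = "Fos", target_channel = "IL34",
                          min_margin = 3L, size_window = c(1, 60)) {
  nuclei <- segment_nuclei(v)
  vvol <- prod(v$voxel_size)
  n <- nuclei$n
  rec <- data.frame(
    nucleus_id = seq_len(n),
    animal_id = animal_id,
    dapi_volume_um3 = nuclei$objects$volume_um3
  )
  puncta_channels <- intersect(setdiff(v$channel_names, "DAPI"), v$channel_names)
  for (ch in puncta_channels) {
    ps <- detect_puncta(v, ch, threshold_method = "midpoint", size_window = size_window)
    asg <- assign_puncta(ps, nuclei)
    rec[[paste0("count_", ch)]] <- asg$counts
    if (asg$n_unassigned > 0L)
      mq_log("fish", "%s: %d puncta unassigned to any nucleus", ch, asg$n_unassigned)
  }
  vg <- rec[[paste0("count_", type_channels[["vglut1"]])]]
  gd <- rec[[paste0("count_", type_channels[["gad2"]])]]
  if (!is.null(vg) && !is.null(gd)) {
    rec$cell_type <- call_cell_type(vg, gd, min_margin)
    n_amb <- sum(rec$cell_type == "ambiguous")
    if (n_amb > 0L) mq_log("fish", "%d ambiguous cell(s) excluded from type averages", n_amb)
  }
  fos <- rec[[paste0("count_", fos_channel)]]
  if (!is.null(fos) && n > 0L) {
    rec$fos_state <- call_fos_state(fos, rec$dapi_volume_um3, median(rec$dapi_volume_um3))
  }
  tg <- rec[[paste0("count_", target_channel)]]
  if (!is.null(tg)) {
    rec$target_density_per_um3 <- tg / rec$dapi_volume_um3
  }
  class(rec) <- c("fish_records", "data.frame")
  rec
}

#' Animal-level mean target density per cell type
#'
#' Averages the DAPI-normalized target density over all non-ambiguous
#' cells of a given type within a given animal; empty strata are omitted
#' with a warning, and the contributing cell n is reported alongside.
#'
#' @param records [quantify_fish()] output (rows from one or more animals).
#' @param by Grouping columns, default animal and cell type; add
#'   `"fos_state"` to stratify by activity.
#' @param measure Column to average.
#' @return Data frame of per-stratum means with `n_cells`.
#' @export
il34_by_type <- function(records, by = c("animal_id", "cell_type"),
                         measure = "target_density_per_um3") {
  df <- records[records$cell_type != "ambiguous", , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no non-ambiguous cells: empty result")
    return(data.frame())
  }
  key <- interaction(df[by], drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(s) {
    row <- s[1, by, drop = FALSE]
    row$mean_density <- mean(s[[measure]])
    row$n_cells <- nrow(s)
    row
  }))
  rownames(out) <- NULL
  out
}
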