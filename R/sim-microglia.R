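# Synthetic microglia volumes: sparse branched cells (spherical soma +
# persistent-random-walk processes) on a dark background, lysosomal blobs
# nested inside cells, and synaptic puncta with a controlled engulfed
# fraction.  Every voxel of every structure is recorded, so the ground
# truth is exact by construction.

normalize3 <- function(v) v / sqrt(sum(v^2))

#' Generate a multi-channel microglia volume with exact ground truth
#'
#' Produces a 4-channel stack (Iba1 = whole cell, CD68 = lysosomes inside
#' cells, VGlut2 = synaptic puncta, TMEM119 = per-cell expression-class
#' intensity) plus a ground-truth object with the generating label grids
#' and exact voxel-derived volumes.  Somas are placed with pairwise
#' separation of at least `max(4*soma_radius,
#' 2*(soma_radius + process_length) + 0.5)` um so that whole cells can
#' never touch; exactly `round(engulfed_fraction * n_synaptic_puncta)`
#' puncta have centroids inside lysosomes, and for a fixed seed the
#' engulfed punctum set is nested across increasing `engulfed_fraction`.
#'
#' @param config A [generator_config()].
#' @return A list with elements `volume` (a [volume_image()]) and `truth`
#'   (class `mg_truth`: cell table, label grids, puncta table).
#' @export
generate_microglia_volume <- function(config) {
  cfg <- validate_config(config)
  dim3 <- cfg$field_shape
  voxel <- cfg$voxel_size
  nvox <- prod(dim3)
  ext <- (dim3 - 1L) * voxel   # physical extent of voxel centres

  with_stage_seed(cfg$seed, "microglia", {
    lab <- integer(nvox)
    lyso <- integer(nvox)
    classes <- character(0)
    centers <- matrix(numeric(0), 0, 3)

    if (cfg$n_cells > 0L) {
      min_sep <- placement_separation(cfg)
      mxy <- cfg$soma_radius + 0.2
      if (ext[1] < 2 * cfg$soma_radius + 0.5)
        stop("field too shallow for the configured soma radius")
      zc <- ext[1] / 2
      lower <- c(max(cfg$soma_radius, zc - 0.5), mxy, mxy)
      upper <- c(min(ext[1] - cfg$soma_radius, zc + 0.5), ext[2] - mxy, ext[3] - mxy)
      if (any(upper < lower)) stop("field too crowded: field smaller than one soma")
      centers <- place_points_min_sep(cfg$n_cells, lower, upper, min_sep)

      for (i in seq_len(cfg$n_cells)) {
        idx <- rasterize_sphere(dim3, voxel, centers[i, ], cfg$soma_radius)
        lab[idx[lab[idx] == 0L]] <- i
        # processes: persistent random walks from the soma surface
        step <- 0.25
        n_steps <- max(1L, as.integer(ceiling(cfg$process_length / step)))
        for (p in seq_len(cfg$n_processes_per_cell)) {
          dir <- normalize3(rnorm(3) * c(0.3, 1, 1))
          pos <- centers[i, ] + cfg$soma_radius * dir
          for (s in seq_len(n_steps)) {
            dir <- normalize3(dir + 0.35 * rnorm(3) * c(0.3, 1, 1))
            pos <- pos + step * dir
            pos <- pmin(pmax(pos, 0.2), ext - 0.2)
            idx <- rasterize_sphere(dim3, voxel, pos, cfg$process_radius)
            sel <- idx[lab[idx] == 0L]
            lab[sel] <- i
          }
        }
      }
      classes <- sample(names(cfg$class_probs), cfg$n_cells,
                        replace = TRUE, prob = cfg$class_probs)
    }

    fg <- which(lab > 0L)
    cell_vox <- if (length(fg)) split(fg, lab[fg]) else list()
    cell_counts <- integer(cfg$n_cells)
    if (cfg$n_cells > 0L)
      cell_counts[as.integer(names(cell_vox))] <- lengths(cell_vox)

    # lysosomal blobs nested inside each cell
    if (cfg$n_cells > 0L && cfg$lysosome_fraction > 0) {
      for (i in seq_len(cfg$n_cells)) {
        cvox <- cell_vox[[as.character(i)]]
        target <- round(cfg$lysosome_fraction * length(cvox))
        placed <- 0L
        tries <- 0L
        while (placed < target && tries < 200L) {
          tries <- tries + 1L
          ctr_idx <- cvox[sample.int(length(cvox), 1L)]
          ctr <- (linear_to_zyx(ctr_idx, dim3)[1, ] - 1) * voxel
          blob <- rasterize_sphere(dim3, voxel, ctr, cfg$lysosome_radius)
          blob <- blob[lab[blob] == i]          # lysosome stays inside its cell
          new <- blob[lyso[blob] == 0L]
          lyso[new] <- i
          placed <- placed + length(new)
        }
      }
    }

    # synaptic puncta: candidate positions are drawn for all n puncta
    # regardless of engulfed_fraction, then the first n_eng in-lysosome
    # candidates are used; increasing the fraction at a fixed seed therefore
    # only adds engulfed puncta (monotone by construction)
    n_p <- if (cfg$n_cells > 0L) cfg$n_synaptic_puncta else 0L  # no cells: background only
    n_eng <- round(cfg$engulfed_fraction * n_p)
    pm <- logical(nvox)
    puncta <- data.frame()
    if (n_p > 0L) {
      lyso_pool <- which(lyso > 0L)
      if (n_eng > 0L && length(lyso_pool) == 0L)
        stop("engulfed_fraction > 0 requires lysosome voxels to host puncta")
      eng_cand <- if (length(lyso_pool) > 0L)
        lyso_pool[sample.int(length(lyso_pool), n_p, replace = length(lyso_pool) < n_p)]
      else integer(0)
      bg_pool <- which(lab == 0L)
      bg_cand <- integer(n_p)
      for (k in seq_len(n_p)) {
        for (t in 1:50) {
          cand <- bg_pool[sample.int(length(bg_pool), 1L)]
          ctr <- (linear_to_zyx(cand, dim3)[1, ] - 1) * voxel
          sph <- rasterize_sphere(dim3, voxel, ctr, cfg$punctum_radius)
          if (!any(lyso[sph] > 0L)) break
        }
        bg_cand[k] <- cand
      }
      centers_idx <- c(if (n_eng > 0L) eng_cand[seq_len(n_eng)] else integer(0),
                       if (n_eng < n_p) bg_cand[(n_eng + 1L):n_p] else integer(0))
      engulfed <- c(rep(TRUE, n_eng), rep(FALSE, n_p - n_eng))
      coords <- (linear_to_zyx(centers_idx, dim3) - 1) *
        matrix(voxel, n_p, 3, byrow = TRUE)
      for (k in seq_len(n_p)) {
        sph <- rasterize_sphere(dim3, voxel, coords[k, ], cfg$punctum_radius)
        pm[sph] <- TRUE
      }
      puncta <- data.frame(
        punctum_id = seq_len(n_p),
        z_um = coords[, 1], y_um = coords[, 2], x_um = coords[, 3],
        engulfed = engulfed,
        cell_id = ifelse(engulfed, lyso[centers_idx], NA_integer_)
      )
    }

    # exact voxel-derived truth volumes
    vvol <- prod(voxel)
    lyso_counts <- integer(cfg$n_cells)
    if (any(lyso > 0L)) {
      tb <- tabulate(lyso[lyso > 0L], nbins = cfg$n_cells)
      lyso_counts <- tb
    }
    eng_counts <- integer(cfg$n_cells)
    eng_idx <- which(pm & lyso > 0L)
    if (length(eng_idx))
      eng_counts <- tabulate(lyso[eng_idx], nbins = cfg$n_cells)

    cells <- data.frame(
      cell_id = seq_len(cfg$n_cells),
      class_label = if (cfg$n_cells > 0L) classes else character(0),
      center_z_um = centers[, 1], center_y_um = centers[, 2], center_x_um = centers[, 3],
      voxel_count = cell_counts,
      volume_um3 = cell_counts * vvol,
      lysosome_voxels = lyso_counts,
      lysosome_volume_um3 = lyso_counts * vvol,
      engulfed_voxels = eng_counts,
      engulfed_volume_um3 = eng_counts * vvol
    )

    # render requested channels: piecewise-constant foreground + Gaussian
    # noise, quantized to integer grey levels
    render <- function(fg_idx, level) {
      img <- cfg$background_level + rnorm(nvox, 0, cfg$noise_sd)
      if (is.list(fg_idx)) {  # per-voxel levels
        img[fg_idx$idx] <- img[fg_idx$idx] - cfg$background_level + fg_idx$level
      } else if (length(fg_idx)) {
        img[fg_idx] <- img[fg_idx] - cfg$background_level + level
      }
      quantize_grey(img)
    }
    chan_data <- list()
    for (ch in cfg$channels) {
      chan_data[[ch]] <- switch(
        ch,
        Iba1 = render(fg, cfg$foreground_level),
        CD68 = render(which(lyso > 0L), cfg$foreground_level),
        VGlut2 = render(which(pm), cfg$foreground_level),
        TMEM119 = {
          lv <- if (length(fg)) cfg$tmem_class_levels[classes[lab[fg]]] else numeric(0)
          render(list(idx = fg, level = lv))
        },
        stop("unknown channel: ", ch)
      )
    }
    data <- stack_channels(chan_data, dim3)

    dim(lab) <- dim3
    dim(lyso) <- dim3
    truth <- structure(list(
      n_cells = cfg$n_cells,
      cells = cells,
      label_grid = lab,
      lysosome_grid = lyso,
      puncta = puncta,
      voxel_size = voxel,
      config = cfg
    ), class = "mg_truth")

    list(volume = new_volume_image(data, voxel, cfg$channels), truth = truth)
  })
}

#' @export
print.mg_truth <- function(x, ...) {
  cat(sprintf("<mg_truth> %d cell(s), %d puncta (%d engulfed)\n",
              x$n_cells, nrow(x$puncta), sum(x$puncta$engulfed)))
  invisible(x)
}
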