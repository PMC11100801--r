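# Synthetic RNA-FISH fields: DAPI nucleus spheres plus per-channel puncta
# whose per-cell counts are drawn from a negative-binomial distribution
# with cell-type-dependent means (excitatory IL34 mean defaults to twice
# the inhibitory mean, the in-vivo condition the pipeline must recover).

#' Generate a nucleus + puncta FISH field with known per-cell counts
#'
#' Channels: DAPI plus one puncta channel per marker named in
#' `fish_type_means` (default VGlut1, Gad2, Fos, IL34).  Nuclei are placed
#' non-touching; each nucleus gets a cell type and per-channel puncta
#' counts `~ NB(mean[type, channel], size = fish_dispersion)`
#' (`fish_dispersion = Inf` gives Poisson counts).  Puncta centroids are
#' placed inside the nucleus with a minimum same-channel spacing so puncta
#' never blend; if a nucleus cannot host all drawn puncta the truth records
#' the placed count.
#'
#' @param config A [generator_config()]; see [config_fish()] for the
#'   standard FISH acquisition geometry.
#' @return List with `volume` (a [volume_image()]) and `truth` (class
#'   `fish_truth`: nucleus table with types and exact per-channel counts,
#'   nucleus label grid).
#' @export
generate_fish_field <- function(config) {
  cfg <- validate_config(config)
  types <- names(cfg$fish_type_means)
  if (length(types) < 2L)
    stop("fish_type_means must name at least two cell types")
  markers <- names(cfg$fish_type_means[[1]])
  for (m in cfg$fish_type_means) {
    if (!identical(names(m), markers))
      stop("all cell types must state means for the same channels")
  }
  dim3 <- cfg$field_shape
  voxel <- cfg$voxel_size
  nvox <- prod(dim3)
  ext <- (dim3 - 1L) * voxel

  with_stage_seed(cfg$seed, "fish", {
    n <- cfg$n_cells
    lab <- integer(nvox)
    nuclei <- data.frame()
    counts <- matrix(0L, 0, length(markers), dimnames = list(NULL, markers))
    puncta_idx <- setNames(vector("list", length(markers)), markers)
    for (mk in markers) puncta_idx[[mk]] <- integer(0)

    if (n > 0L) {
      r <- cfg$nucleus_radius
      if (ext[1] < 2 * r + 0.5) stop("field too shallow for the configured nucleus radius")
      zc <- ext[1] / 2
      lower <- c(max(r, zc - 0.5), r + 0.2, r + 0.2)
      upper <- c(min(ext[1] - r, zc + 0.5), ext[2] - r - 0.2, ext[3] - r - 0.2)
      centers <- place_points_min_sep(n, lower, upper, 2 * r + 2)
      # balanced type assignment, randomly ordered
      base <- rep(types, length.out = n)
      type <- sample(base, n)

      counts <- matrix(0L, n, length(markers), dimnames = list(NULL, markers))
      nuc_vox <- vector("list", n)
      core_vox <- vector("list", n)
      # puncta centres are drawn from an eroded core so each punctum sphere
      # stays wholly inside its nucleus (centroid containment then exact)
      core_r <- max(r - cfg$punctum_radius - max(voxel), 0.5 * r)
      for (i in seq_len(n)) {
        idx <- rasterize_sphere(dim3, voxel, centers[i, ], r)
        lab[idx] <- i
        nuc_vox[[i]] <- idx
        core_vox[[i]] <- rasterize_sphere(dim3, voxel, centers[i, ], core_r)
      }
      # spacing rule: with one voxel-diagonal-and-a-half of clearance two
      # rasterized puncta can never be 26-connected, so detected component
      # counts equal planted counts
      min_gap <- 2 * cfg$punctum_radius + 1.6 * max(cfg$voxel_size)
      for (i in seq_len(n)) {
        mus <- cfg$fish_type_means[[type[i]]]
        for (mk in markers) {
          k <- if (is.finite(cfg$fish_dispersion)) {
            rnbinom(1L, mu = mus[[mk]], size = cfg$fish_dispersion)
          } else {
            rpois(1L, mus[[mk]])
          }
          placed <- matrix(numeric(0), 0, 3)
          pool <- core_vox[[i]]
          for (p in seq_len(k)) {
            ok <- FALSE
            for (t in 1:60) {
              cand <- pool[sample.int(length(pool), 1L)]
              pos <- (linear_to_zyx(cand, dim3)[1, ] - 1) * voxel
              if (nrow(placed) == 0L ||
                  all((placed[, 1] - pos[1])^2 + (placed[, 2] - pos[2])^2 +
                        (placed[, 3] - pos[3])^2 >= min_gap^2)) {
                ok <- TRUE
                break
              }
            }
            if (!ok) break   # nucleus saturated; truth records placed count
            placed <- rbind(placed, pos)
            sph <- rasterize_sphere(dim3, voxel, pos, cfg$punctum_radius)
            puncta_idx[[mk]] <- c(puncta_idx[[mk]], sph)
            counts[i, mk] <- counts[i, mk] + 1L
          }
        }
      }
      vvol <- prod(voxel)
      nuc_counts <- lengths(nuc_vox)
      nuclei <- data.frame(
        nucleus_id = seq_len(n),
        cell_type = type,
        center_z_um = centers[, 1], center_y_um = centers[, 2], center_x_um = centers[, 3],
        voxel_count = nuc_counts,
        dapi_volume_um3 = nuc_counts * vvol
      )
      nuclei <- cbind(nuclei, as.data.frame(counts))
    }

    render <- function(fg_idx) {
      img <- cfg$background_level + rnorm(nvox, 0, cfg$noise_sd)
      img[fg_idx] <- cfg$foreground_level + rnorm(length(fg_idx), 0, cfg$noise_sd)
      quantize_grey(img)
    }
    channels <- c("DAPI", markers)
    chan_data <- c(list(render(which(lab > 0L))),
                   lapply(markers, function(mk) render(unique(puncta_idx[[mk]]))))
    data <- stack_channels(chan_data, dim3)

    dim(lab) <- dim3
    truth <- structure(list(
      n_cells = n,
      nuclei = nuclei,
      nucleus_grid = lab,
      markers = markers,
      voxel_size = voxel,
      config = cfg
    ), class = "fish_truth")
    list(volume = new_volume_image(data, voxel, channels), truth = truth)
  })
}
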