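# Synthetic pre/postsynaptic puncta fields: a controlled number of
# colocalized pairs (pre and post discs overlapping) plus isolated singles
# kept far apart, so the true colocalized pair count is exact.

#' Generate a two-channel synaptic puncta field
#'
#' `round(coloc_probability * min(n_pre, n_post))` pre/post pairs are
#' planted with centroid offsets small enough to guarantee voxel overlap;
#' all remaining puncta are isolated by at least `min_sep` um from every
#' other punctum of either channel, so they satisfy neither the overlap nor
#' a centroid criterion up to `min_sep - 2 * punctum_radius`.
#'
#' @param config A [generator_config()]; uses `n_pre_puncta`,
#'   `n_post_puncta`, `coloc_probability`, `punctum_radius`.
#' @param min_sep Minimum separation between non-paired puncta centres (um).
#' @return List with `volume` (channels `VGlut2`, `PSD95`) and `truth`
#'   (class `syn_truth` with `colocalized_pair_count` and per-punctum
#'   centroid tables).
#' @export
generate_synapse_field <- function(config, min_sep = 3) {
  cfg <- validate_config(config)
  dim3 <- cfg$field_shape
  voxel <- cfg$voxel_size
  nvox <- prod(dim3)
  ext <- (dim3 - 1L) * voxel

  with_stage_seed(cfg$seed, "synapse", {
    n_pre <- cfg$n_pre_puncta
    n_post <- cfg$n_post_puncta
    n_pair <- round(cfg$coloc_probability * min(n_pre, n_post))
    n_sites <- n_pair + (n_pre - n_pair) + (n_post - n_pair)
    margin <- cfg$punctum_radius + 0.5
    zc <- ext[1] / 2
    lower <- c(max(0, zc - 0.2), margin, margin)
    upper <- c(min(ext[1], zc + 0.2), ext[2] - margin, ext[3] - margin)
    sites <- if (n_sites > 0L)
      place_points_min_sep(n_sites, lower, upper, min_sep)
    else matrix(numeric(0), 0, 3)

    pre_centers <- matrix(numeric(0), 0, 3)
    post_centers <- matrix(numeric(0), 0, 3)
    if (n_pair > 0L) {
      anchors <- sites[seq_len(n_pair), , drop = FALSE]
      theta <- runif(n_pair, 0, 2 * pi)
      off_r <- runif(n_pair, 0, 0.6 * cfg$punctum_radius)
      offs <- cbind(0, off_r * sin(theta), off_r * cos(theta))
      pre_centers <- anchors
      post_centers <- anchors + offs
    }
    if (n_pre > n_pair)
      pre_centers <- rbind(pre_centers, sites[n_pair + seq_len(n_pre - n_pair), , drop = FALSE])
    if (n_post > n_pair)
      post_centers <- rbind(post_centers,
                            sites[n_pair + (n_pre - n_pair) + seq_len(n_post - n_pair), , drop = FALSE])

    stamp <- function(centers) {
      m <- logical(nvox)
      for (k in seq_len(nrow(centers))) {
        m[rasterize_sphere(dim3, voxel, centers[k, ], cfg$punctum_radius)] <- TRUE
      }
      m
    }
    pre_m <- stamp(pre_centers)
    post_m <- stamp(post_centers)

    render <- function(fg) {
      img <- cfg$background_level + rnorm(nvox, 0, cfg$noise_sd)
      img[fg] <- cfg$foreground_level + rnorm(sum(fg), 0, cfg$noise_sd)
      quantize_grey(img)
    }
    data <- stack_channels(list(render(pre_m), render(post_m)), dim3)

    centers_df <- function(centers) {
      data.frame(z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3])
    }
    truth <- structure(list(
      n_pre = n_pre, n_post = n_post,
      colocalized_pair_count = n_pair,
      pre_centers = centers_df(pre_centers),
      post_centers = centers_df(post_centers),
      min_sep = min_sep,
      config = cfg
    ), class = "syn_truth")
    list(volume = new_volume_image(data, voxel, c("VGlut2", "PSD95")), truth = truth)
  })
}

#' Preset: synapse-field acquisition geometry
#'
#' A thin (single-plane-like) high-resolution field sized to hold the
#' requested puncta at the enforced separation.
#'
#' @param seed Integer seed.
#' @param n_pre,n_post Puncta counts.
#' @param coloc_probability Planted colocalized fraction.
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
config_synapse <- function(seed = 1L, n_pre = 200L, n_post = 200L,
                           coloc_probability = 0.5, ...) {
  n_sites <- n_pre + n_post  # upper bound on placed sites
  side_um <- max(30, ceiling(sqrt(n_sites * pi * 1.5^2 / 0.30)))
  n_px <- as.integer(ceiling(side_um / 0.1))
  generator_config(
    seed = seed,
    field_shape = c(1L, n_px, n_px),
    voxel_size = c(0.33, 0.1, 0.1),
    n_pre_puncta = n_pre, n_post_puncta = n_post,
    coloc_probability = coloc_probability,
    ...
  )
}
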