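# Generator configuration: one validated object drives every synthetic
# field.  Defaults encode the study conditions the generators emulate
# (60x/0.33 um engulfment stacks, 20x/1 um counting stacks); presets below
# adjust the acquisition geometry per assay.

#' Configuration for the synthetic-microscopy generators
#'
#' All lengths are micrometres, intensities are integer grey levels
#' (camera-count scale).  A fixed `seed` makes every generator output
#' bit-identical; each generator derives its own RNG stream from
#' `(seed, stage-name)` so stages are independently reproducible.
#'
#' @param seed Integer seed.
#' @param field_shape Grid `(nz, ny, nx)` in voxels.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param n_cells Number of cells (microglia or nuclei) to plant.
#' @param soma_radius Soma radius (um).
#' @param n_processes_per_cell Processes per microglia.
#' @param process_length Process length (um), walked from the soma surface.
#' @param process_radius Process tube radius (um).
#' @param lysosome_fraction Target fraction of each cell's volume occupied
#'   by lysosomes, in `[0, 1]`.
#' @param lysosome_radius Radius of individual lysosomal blobs (um).
#' @param n_synaptic_puncta Total synaptic (VGlut2) puncta in the field.
#' @param engulfed_fraction Fraction of synaptic puncta whose centroids are
#'   placed inside lysosomes, in `[0, 1]`.
#' @param punctum_radius Punctum radius (um).
#' @param background_level,foreground_level Grey levels of background and
#'   stained structures.
#' @param noise_sd Additive Gaussian noise standard deviation (grey levels).
#' @param tmem_class_levels Named grey levels for the Lo/Mid/Hi TMEM119
#'   expression classes assigned to cells.
#' @param class_probs Probabilities of the Lo/Mid/Hi classes.
#' @param nucleus_radius Nucleus (DAPI) radius for FISH fields (um).
#' @param fish_type_means Named list: per cell type, named mean puncta
#'   counts per FISH channel.
#' @param fish_dispersion Negative-binomial size parameter for puncta
#'   counts; `Inf` gives Poisson counts.
#' @param n_pre_puncta,n_post_puncta Pre/postsynaptic puncta counts for
#'   synapse fields.
#' @param coloc_probability Fraction of puncta planted as colocalized
#'   pre/post pairs, in `[0, 1]`.
#' @param channels Channel subset to render for microglia volumes.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(
    seed = 1L,
    field_shape = c(30L, 560L, 560L),
    voxel_size = c(0.33, 0.1, 0.1),
    n_cells = 10L,
    soma_radius = 2.5,
    n_processes_per_cell = 4L,
    process_length = 2.5,
    process_radius = 0.4,
    lysosome_fraction = 0.05,
    lysosome_radius = 0.8,
    n_synaptic_puncta = 60L,
    engulfed_fraction = 0.25,
    punctum_radius = 0.3,
    background_level = 20,
    foreground_level = 150,
    noise_sd = 10,
    tmem_class_levels = c(Lo = 60, Mid = 110, Hi = 160),
    class_probs = c(Lo = 1, Mid = 1, Hi = 1) / 3,
    nucleus_radius = 3.5,
    fish_type_means = list(
      glutamatergic = c(VGlut1 = 10, Gad2 = 0.5, IL34 = 10),
      GABAergic     = c(VGlut1 = 0.5, Gad2 = 10, IL34 = 5)
    ),
    fish_dispersion = 8,
    n_pre_puncta = 200L,
    n_post_puncta = 200L,
    coloc_probability = 0.5,
    channels = c("Iba1", "CD68", "VGlut2", "TMEM119")) {
  cfg <- list(
    seed = as.integer(seed),
    field_shape = as.integer(field_shape),
    voxel_size = as.numeric(voxel_size),
    n_cells = as.integer(n_cells),
    soma_radius = soma_radius,
    n_processes_per_cell = as.integer(n_processes_per_cell),
    process_length = process_length,
    process_radius = process_radius,
    lysosome_fraction = lysosome_fraction,
    lysosome_radius = lysosome_radius,
    n_synaptic_puncta = as.integer(n_synaptic_puncta),
    engulfed_fraction = engulfed_fraction,
    punctum_radius = punctum_radius,
    background_level = background_level,
    foreground_level = foreground_level,
    noise_sd = noise_sd,
    tmem_class_levels = tmem_class_levels,
    class_probs = class_probs,
    nucleus_radius = nucleus_radius,
    fish_type_means = fish_type_means,
    fish_dispersion = fish_dispersion,
    n_pre_puncta = as.integer(n_pre_puncta),
    n_post_puncta = as.integer(n_post_puncta),
    coloc_probability = coloc_probability,
    channels = channels
  )
  class(cfg) <- "generator_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  frac <- c(lysosome_fraction = cfg$lysosome_fraction,
            engulfed_fraction = cfg$engulfed_fraction,
            coloc_probability = cfg$coloc_probability)
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1))
    stop("all fractions must lie in [0, 1]")
  pos <- c(cfg$voxel_size, cfg$soma_radius, cfg$process_radius,
           cfg$lysosome_radius, cfg$punctum_radius, cfg$nucleus_radius,
           cfg$noise_sd + 1e-12, cfg$foreground_level)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all physical extents and levels must be strictly positive")
  if (length(cfg$field_shape) != 3L || any(cfg$field_shape < 1L))
    stop("field_shape must be three positive voxel counts (nz, ny, nx)")
  if (cfg$n_cells < 0L || cfg$n_synaptic_puncta < 0L ||
      cfg$n_pre_puncta < 0L || cfg$n_post_puncta < 0L)
    stop("counts must be non-negative")
  if (!is.null(cfg$fish_type_means)) {
    for (m in cfg$fish_type_means) {
      if (any(!is.finite(m)) || any(m <= 0)) stop("fish_type_means must be strictly positive")
    }
  }
  if (abs(sum(cfg$class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> seed=%d, field %s voxels @ %s um, %d cells\n",
              x$seed, paste(x$field_shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"), x$n_cells))
  invisible(x)
}

#' Preset: 20x counting-field acquisition geometry
#'
#' 19 z-planes at 1 um spacing, 0.5 um lateral sampling; the field side is
#' scaled to the number of planted cells so that placement stays feasible at
#' the enforced separation.
#'
#' @param n_cells Cells to plant.
#' @param seed Integer seed.
#' @param ... Further overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
config_counting <- function(n_cells, seed = 1L, ...) {
  cfg0 <- generator_config(seed = seed, n_cells = n_cells, ...)
  sep <- placement_separation(cfg0)
  side_um <- max(40, ceiling(sqrt(max(1L, n_cells) * pi * (sep / 2)^2 / 0.30)))
  n_px <- as.integer(ceiling(side_um / 0.5))
  generator_config(
    seed = seed, n_cells = n_cells,
    field_shape = c(19L, n_px, n_px),
    voxel_size = c(1, 0.5, 0.5),
    lysosome_fraction = 0,
    n_synaptic_puncta = 0L,
    engulfed_fraction = 0,
    channels = "Iba1",
    ...
  )
}

# cells (soma + processes) may never touch: somas are separated by twice
# the maximal process reach, and never less than 4 soma radii
placement_separation <- function(cfg) {
  max(4 * cfg$soma_radius, 2 * (cfg$soma_radius + cfg$process_length) + 0.5)
}

#' Preset: RNA-FISH acquisition geometry
#'
#' 0.5 um z-steps with 0.3 um lateral sampling; the lateral field side is
#' scaled to hold `n_cells` non-touching nuclei.
#'
#' @param n_cells Nuclei to plant.
#' @param seed Integer seed.
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
config_fish <- function(n_cells = 400L, seed = 1L, ...) {
  cfg0 <- generator_config(seed = seed, n_cells = n_cells, ...)
  sep <- 2 * cfg0$nucleus_radius + 2
  side_um <- max(30, ceiling(sqrt(max(1L, n_cells) * pi * (sep / 2)^2 / 0.35)))
  n_px <- as.integer(ceiling(side_um / 0.3))
  nz <- as.integer(ceiling((2 * cfg0$nucleus_radius + 1) / 0.5))
  generator_config(
    seed = seed, n_cells = n_cells,
    field_shape = c(nz, n_px, n_px),
    voxel_size = c(0.5, 0.3, 0.3),
    ...
  )
}

#' Preset: 60x engulfment-field acquisition geometry (package default)
#'
#' 0.33 um z-steps with 0.1 um lateral sampling, four channels.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
config_engulfment <- function(seed = 1L, ...) {
  generator_config(seed = seed, ...)
}
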