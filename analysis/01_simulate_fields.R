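#!/usr/bin/env Rscript
# Generate one small example of each synthetic field (engulfment stack,
# FISH field, synapse field, Sholl star phantom), write them as TIFF +
# JSON-sidecar under results/fields/, and summarize their ground truth.

suppressPackageStartupMessages(library(microquant))
dir.create("results/fields", showWarnings = FALSE, recursive = TRUE)
seed <- 1L

eng <- generate_microglia_volume(generator_config(
  seed = seed, n_cells = 4L, field_shape = c(30L, 370L, 370L)))
write_volume(eng$volume, "results/fields/engulfment_demo.tif")
write_result_table(eng$truth$cells, "results/fields/engulfment_truth.csv",
                   config = eng$truth$config, seed = seed)
message(sprintf("engulfment demo: %d cells, %.1f%% mean lysosome fraction, %d puncta (%d engulfed)",
                eng$truth$n_cells, mean(truth_capacity(eng$truth)),
                nrow(eng$truth$puncta), sum(eng$truth$puncta$engulfed)))

fish <- generate_fish_field(config_fish(60, seed = seed))
write_volume(fish$volume, "results/fields/fish_demo.tif")
write_result_table(fish$truth$nuclei, "results/fields/fish_truth.csv",
                   config = fish$truth$config, seed = seed)
message(sprintf("fish demo: %d nuclei (%s)", fish$truth$n_cells,
                paste(names(table(fish$truth$nuclei$cell_type)),
                      table(fish$truth$nuclei$cell_type), collapse = ", ")))

syn <- generate_synapse_field(config_synapse(seed = seed, n_pre = 120,
                                             n_post = 120,
                                             coloc_probability = 0.5))
write_volume(syn$volume, "results/fields/synapse_demo.tif")
message(sprintf("synapse demo: %d pre, %d post, %d true colocalized pairs",
                syn$truth$n_pre, syn$truth$n_post,
                syn$truth$colocalized_pair_count))

star <- generate_sholl_phantom(6, arm_length = 20)
write_volume(star$image, "results/fields/sholl_star.tif")
message("sholl star phantom: 6 arms, truth = 6 intersections on every ring inside the arms")
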