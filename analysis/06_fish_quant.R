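#!/usr/bin/env Rscript
# Single-cell RNA-FISH scoring: segment nuclei, count puncta per cell,
# call glutamatergic/GABAergic types, and recover the two-fold
# excitatory/inhibitory target density ratio.

suppressPackageStartupMessages(library(microquant))
dir.create("results", showWarnings = FALSE)

recs <- list()
for (s in 1:3) {
  f <- generate_fish_field(config_fish(200, seed = 60 + s))
  recs[[s]] <- suppressMessages(quantify_fish(f$volume,
                                              animal_id = sprintf("animal%02d", s)))
}
rec <- do.call(rbind, recs)
write_result_table(rec, "results/fish_cells.csv", seed = 60L)

agg <- il34_by_type(rec)
write_result_table(agg, "results/fish_by_type.csv", seed = 60L)
ratios <- vapply(split(agg, agg$animal_id), function(a) {
  a$mean_density[a$cell_type == "glutamatergic"] /
    a$mean_density[a$cell_type == "GABAergic"]
}, numeric(1))
message(sprintf("per-animal excitatory/inhibitory density ratio: %s (target 2.0)",
                paste(round(ratios, 2), collapse = ", ")))
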