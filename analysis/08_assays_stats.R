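#!/usr/bin/env Rscript
# Molecular assays and the animal-level statistics contract: 2^-ddCt fold
# changes from triplicate Ct tables, ELISA per-total-protein
# normalization, and the sex-first factorial comparison on animal means.

suppressPackageStartupMessages(library(microquant))
dir.create("results", showWarnings = FALSE)

tb <- generate_assay_table(seed = 81, fold_changes = c(control = 1, treated = 4))
fc <- suppressMessages(ddct_table(tb, control_group = "control"))
write_result_table(fc, "results/qpcr_fold_changes.csv", seed = 81L)
gm <- tapply(fc$fold_change, fc$group, mean)
message(sprintf("2^-ddCt fold change: control %.2f, treated %.2f (true 4)",
                gm[["control"]], gm[["treated"]]))

per_sample <- tb[!duplicated(tb$sample_id), ]
per_sample$pg_per_100mg <- elisa_normalize(per_sample$elisa_pg_per_ml,
                                           per_sample$total_protein_mg_per_ml)
write_result_table(per_sample, "results/elisa_normalized.csv", seed = 81L)
em <- tapply(per_sample$pg_per_100mg, per_sample$group, mean)
message(sprintf("ELISA pg/100 mg protein: control %.2f, treated %.2f",
                em[["control"]], em[["treated"]]))

study <- simulate_group_study(seed = 82, fold_change = 2)
gc <- suppressMessages(group_compare(study, list(response = "value",
                                                 factors = "group")))
write_result_table(gc$pairwise, "results/group_comparison.csv", seed = 82L)
message(sprintf("group effect p = %.4g (sex %s), Sidak-adjusted contrast p = %.4g",
                effect_p_value(gc),
                if (gc$sex_pooled) "pooled" else "retained",
                gc$pairwise$p.value[1]))
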