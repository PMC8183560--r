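#!/usr/bin/env Rscript
# Stage 1: build the synthetic FMT trial cohort every later stage
# analyzes.  Full-scale defaults: 52 patients randomized 1:1, 4 donors,
# 2,000 ASVs, depths 6,483-113,847, ~20% of follow-up visits missing,
# with planted gains/losses/transient colonizations in the FMT arm.

suppressPackageStartupMessages(library(fmtengraft))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(rng_seed = 42)
sim <- simulate_cohort(cfg)

write_feature_table(sim$table, file.path(out, "feature_table.tsv"))
write_metadata(sim$meta, file.path(out, "metadata.tsv"))
ape::write.tree(sim$tree, file.path(out, "tree.nwk"))
write_truth_events(sim$truth, file.path(out, "truth_events.tsv"))
utils::write.table(as.data.frame(sim$truth$clinical),
                   file.path(out, "truth_clinical.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(as.data.frame(sim$truth$diversity_class),
                   file.path(out, "truth_diversity_class.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(as.data.frame(sim$taxonomy),
                   file.path(out, "taxonomy.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cov <- coverage(sim$table)
cat(sprintf("cohort: %d samples x %d ASVs; depth %d-%d\n",
            nrow(sim$table), ncol(sim$table), min(cov), max(cov)))
cat(sprintf("patients: %d FMT, %d placebo, %d donors; %d planted events\n",
            cfg$n_fmt_patients, cfg$n_placebo_patients, cfg$n_donors,
            nrow(sim$truth$events)))
cat("wrote", out, "\n")
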