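#!/usr/bin/env Rscript
# Stage 2: alpha diversity per sample, donor-anchored low/normal
# classification of baseline diversity, and change-from-baseline tests.

suppressPackageStartupMessages(library(fmtengraft))

ft <- read_feature_table("results/data/feature_table.tsv")
meta <- read_metadata("results/data/metadata.tsv")
out <- "results/alpha"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

div <- diversity_table(ft)
classes <- initial_diversity_classes(ft, meta)
change <- diversity_change_table(div, meta, metric = "chao1")

utils::write.table(as.data.frame(div), file.path(out, "diversity.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(as.data.frame(classes),
                   file.path(out, "diversity_classes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(as.data.frame(change$tests),
                   file.path(out, "change_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("initial-diversity classes:\n")
print(table(classes$arm, classes$class))
fmt <- change$tests[change$tests$arm %in% "FMT", ]
cat(sprintf("FMT mean dChao1 positive at %d/%d follow-ups (max p = %.2g)\n",
            sum(fmt$mean_delta > 0), nrow(fmt), max(fmt$p_value)))
pla <- change$tests[change$tests$arm %in% "placebo", ]
cat(sprintf("placebo mean dChao1 range %.1f..%.1f (min p = %.2g)\n",
            min(pla$mean_delta), max(pla$mean_delta), min(pla$p_value)))
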