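#!/usr/bin/env Rscript
# Stage 3: generalized UniFrac distances of every patient sample to the
# donors, Mann-Whitney change tests per arm, and a PCoA of all samples.

suppressPackageStartupMessages(library(fmtengraft))

ft <- read_feature_table("results/data/feature_table.tsv")
meta <- read_metadata("results/data/metadata.tsv")
tree <- read_tree("results/data/tree.nwk")
out <- "results/beta"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dd <- donor_distance_course(ft, meta, tree, alpha = 0.5)
utils::write.table(as.data.frame(dd$distances),
                   file.path(out, "donor_distances.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(as.data.frame(dd$tests),
                   file.path(out, "donor_distance_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

dm <- unifrac_matrix(ft, tree, "generalized", alpha = 0.5)
ord <- pcoa(dm, n_axes = 2)
coords <- data.frame(sample_id = ord$ids, ord$coordinates)
utils::write.table(coords, file.path(out, "pcoa_coordinates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(as.data.frame(dm), file.path(out, "distance_matrix.tsv"),
                   sep = "\t", quote = FALSE, row.names = TRUE)

cat("donor-distance change tests:\n")
print(as.data.frame(dd$tests), digits = 3)
cat(sprintf("PCoA axes 1-2 explain %.0f%% + %.0f%% of positive inertia\n",
            100 * ord$proportion_explained[1],
            100 * ord$proportion_explained[2]))
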