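#!/usr/bin/env Rscript
# Stage 6: clinical response / severity classification and the
# statistical screens: differential ASV abundance per time-point and
# Spearman correlation of diversity change against symptom change.

suppressPackageStartupMessages({
  library(fmtengraft)
  library(dplyr)
})

ft <- read_feature_table("results/data/feature_table.tsv")
meta <- read_metadata("results/data/metadata.tsv")
out <- "results/clinical"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

clinical <- clinical_status(meta)
utils::write.table(as.data.frame(clinical),
                   file.path(out, "clinical_status.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("responders by arm:\n")
print(table(clinical$arm, clinical$responder, useNA = "ifany"))
cat("severity at baseline / m3:\n")
print(table(clinical$arm, clinical$severity_baseline))
print(table(clinical$arm, clinical$severity_m3))

screens <- lapply(c("d15", "m1", "m3", "m6"), function(tp) {
  res <- tryCatch(differential_abundance(ft, meta, timepoint = tp),
                  error = function(e) NULL)
  if (is.null(res)) return(NULL)
  res$timepoint <- tp
  res
})
screens <- bind_rows(screens)
utils::write.table(as.data.frame(screens),
                   file.path(out, "differential_abundance.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
sig <- screens |> group_by(timepoint) |> summarise(n_sig = sum(significant))
cat("significant ASVs (BH <= 0.05), FMT vs placebo:\n")
print(as.data.frame(sig))

# diversity change vs symptom change at m3
div <- diversity_table(ft)
ch <- diversity_change_table(div, meta, metric = "chao1")
d_m3 <- ch$deltas[ch$deltas$timepoint == "m3", ]
merged <- merge(d_m3, clinical, by = "subject_id")
merged$delta_sss <- merged$m3_sss - merged$baseline_sss
sp <- spearman_screen(merged$delta, merged$delta_sss)
utils::write.table(as.data.frame(sp),
                   file.path(out, "diversity_symptom_screen.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("dChao1 vs dIBS-SSS at m3: rho = %.2f, R2 = %.2f, p = %.2g -> %s\n",
            sp$rho, sp$r_squared, sp$p_value,
            ifelse(sp$pass, "passes criteria", sp$reason)))
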