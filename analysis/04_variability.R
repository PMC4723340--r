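#!/usr/bin/env Rscript
# Fold-change variability of the expressed genes: per gene the maximum
# fold change over all 24 eggs and the maximum within any single clutch.
# The contrast between the two shows how much of the variability is
# between mothers rather than between eggs of one mother.

suppressPackageStartupMessages(library(clutchsig))

out_dir <- "results/data"
m <- read_probe_matrix(file.path(out_dir, "intensities_norm.tsv"),
                       file.path(out_dir, "samples.tsv"))
calls <- read.delim(file.path(out_dir, "gene_calls.tsv"))

rep_probe <- setNames(calls$representative_probe, calls$gene_id)
expressed <- calls$gene_id[calls$expressed]
gm <- gene_matrix(m, rep_probe, expressed)
cl <- clutch_factor(m)

tb <- mfc_table(gm, cl)
sm <- mfc_summary(tb, thresholds = c(2, 4))
print(sm)
message(sprintf("%.0f%% of expressed genes: within-clutch mFC <= 2 (experiment-wide: %.0f%%)",
                100 * sm$frac_within_clutch[1], 100 * sm$frac_experiment[1]))

write.table(tb, file.path(out_dir, "mfc_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(sm, file.path(out_dir, "mfc_summary.json"),
                     auto_unbox = TRUE, digits = NA)
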