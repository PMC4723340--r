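#!/usr/bin/env Rscript
# Differential expression between clutches: per-gene one-way ANOVA with
# clutch as the factor, Storey q-values at FDR < 5%. Even genes with
# small overall variability tend to differ between mothers.

suppressPackageStartupMessages(library(clutchsig))

out_dir <- "results/data"
m <- read_probe_matrix(file.path(out_dir, "intensities_norm.tsv"),
                       file.path(out_dir, "samples.tsv"))
calls <- read.delim(file.path(out_dir, "gene_calls.tsv"))

rep_probe <- setNames(calls$representative_probe, calls$gene_id)
expressed <- calls$gene_id[calls$expressed]
gm <- gene_matrix(m, rep_probe, expressed)

res <- diffexp_table(gm, clutch_factor(m), fdr = 0.05)
message(sprintf("pi0 estimate: %.2f", attr(res, "pi0")))
message(sprintf("%d of %d expressed genes (%.1f%%) differential between clutches at FDR 5%%",
                sum(res$significant), nrow(res),
                100 * mean(res$significant)))

write.table(res, file.path(out_dir, "diffexp.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
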