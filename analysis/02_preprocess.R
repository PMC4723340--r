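#!/usr/bin/env Rscript
# Quality filtering and between-array normalization: drop genes with one
# unrealistically extreme sample, flag and drop probes whose signal
# anti-correlates with the array scaling factors (native poly(A) tails),
# then quantile-normalize between arrays.

suppressPackageStartupMessages(library(clutchsig))

out_dir <- "results/data"
m <- read_probe_matrix(file.path(out_dir, "intensities_raw.tsv"),
                       file.path(out_dir, "samples.tsv"))
ann <- read.delim(file.path(out_dir, "annotation.tsv"))

ext <- remove_extreme_genes(m, ann, fc_threshold = 3000)
message(sprintf("extreme-gene filter removed %d gene(s)",
                length(unique(ext$report$gene_id))))

qc <- detect_suspect_probes(ext$matrix, corr_cut = -0.8)
message(sprintf("suspect-probe filter flagged %d of %d probes",
                sum(qc$suspect), nrow(qc)))
filtered <- drop_suspect_probes(ext$matrix, qc)

norm <- quantile_normalize(filtered)
spread <- mad(colMeans(norm$values))
message(sprintf("post-normalization MAD of column means: %.2e", spread))

write_probe_matrix(norm, file.path(out_dir, "intensities_norm.tsv"))
write.table(qc, file.path(out_dir, "qc_suspect_probes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# how well does the anti-correlation statistic isolate the planted
# native-poly(A) probes?
truth <- jsonlite::fromJSON(file.path(out_dir, "truth.json"))
worst <- qc$probe_id[order(qc$anti_correlation)][seq_along(truth$native_probes)]
message(sprintf("%d/%d native-poly(A) probes rank lowest on anti-correlation",
                length(intersect(worst, truth$native_probes)),
                length(truth$native_probes)))
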