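#!/usr/bin/env Rscript
# Downstream characterization of the expressed genes and the signature
# clusters: 3'UTR motif enrichment (polyadenylation hexamers, CPEs, PBE,
# embryonic poly-U CPEs), hypergeometric overrepresentation of miRNA
# target sets, and Ward clustering of the clusters' chromosome
# distributions, which pairs clusters with their inverse profiles.

suppressPackageStartupMessages(library(clutchsig))

out_dir <- "results/data"
calls <- read.delim(file.path(out_dir, "gene_calls.tsv"))
ann <- read.delim(file.path(out_dir, "annotation.tsv"))
memb <- read.delim(file.path(out_dir, "cluster_membership.tsv"),
                   colClasses = c("character", "character"))

expressed <- calls$gene_id[calls$expressed]
nonexpr <- calls$gene_id[!calls$expressed]

## 3'UTR motif enrichment, expressed vs non-expressed.
## UTRs are synthetic: CPE-like elements are planted into a majority of
## expressed-gene UTRs to emulate the polyadenylation signal structure of
## stored maternal transcripts.
set.seed(20160122)
planted <- list(AAUAAA = sample(expressed, round(0.6 * length(expressed))),
                UUUUUUUUUUU = sample(expressed, round(0.3 * length(expressed))))
utrs <- generate_utrs(calls$gene_id, planted, length = 200, seed = 20160123)
write_utr_fasta(utrs, file.path(out_dir, "utrs_synthetic.fasta"))
enr <- motif_enrichment(utrs[expressed], utrs[nonexpr])
write.table(enr, file.path(out_dir, "motif_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
top <- enr[enr$p_adjusted < 0.05, ]
message(sprintf("motifs enriched in expressed-gene UTRs: %s",
                paste(top$motif_id, collapse = ", ")))

## miRNA-target overrepresentation (synthetic target table biased toward
## expressed genes, mimicking maternal-clearance miRNAs)
set.seed(20160124)
targets <- list(miR_430 = c(sample(expressed, 150), sample(nonexpr, 30)),
                miR_ctrl = sample(calls$gene_id, 180))
hg <- do.call(rbind, lapply(names(targets), function(mi) {
  h <- hypergeom_overrep(expressed, targets[[mi]], calls$gene_id)
  data.frame(mirna = mi, overlap = h$overlap, p_value = h$p_value)
}))
print(hg)
write.table(hg, file.path(out_dir, "mirna_overrep.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## chromosome distribution of the signature clusters, Ward-clustered
g2c <- setNames(ann$chromosome, ann$gene_id)
clusters <- split(memb$gene_id, memb$code)
clusters <- clusters[lengths(clusters) >= 10]
if (length(clusters) >= 2) {
  frac <- chromosome_fraction_matrix(clusters, g2c)
  wc <- ward_cluster_rows(frac)
  message(sprintf("%d clusters clustered by chromosome profile; %d inverse pairs merged first",
                  nrow(frac), nrow(wc$inverse_pairs_merged)))
  write.table(data.frame(code = rownames(frac), frac, check.names = FALSE),
              file.path(out_dir, "chromosome_fractions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
} else {
  message("too few clusters of size >= 10 for chromosome clustering")
}
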