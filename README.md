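# clutchsig

Analysis of maternal transcriptome composition in individual unfertilized
eggs sampled in clutches — several eggs per mother, one clutch per
mother. The package answers two questions about probe-level microarray
intensities from such a design: **which genes are maternally expressed at
all**, and **whether between-egg variability carries a mother-specific
signature**.

The core procedures:

- **Expressed-gene calling from variance bimodality.** The log variance
  of each probe's log2 intensity across the experiment is bimodal: the
  valley between the low-variance (non-expressed) and high-variance
  (expressed) populations is located on a kernel density estimate, and a
  per-array Bayes posterior
  `P(expressed | x) = πₕ fₕ(x) / (πₕ fₕ(x) + πₗ fₗ(x))`
  calls each probe per egg (threshold 0.95, expressed on ≥ 4 arrays ⇒
  expressed transcript; any expressed transcript ⇒ expressed gene).
- **Fold-change variability.** Per gene the maximum fold change over all
  eggs and the maximum within any single clutch — the contrast that shows
  variability is dominated by mother, not egg.
- **Mother signatures.** Genes whose per-clutch intensity ranges split
  into absolutely distinct levels (strict gap; closed-interval overlap)
  get a profile code — one digit per mother, 1 = highest level — and
  genes sharing a code form signature clusters, with inverse-profile
  pairing (1 ↔ 2).
- **Differential expression.** Per-gene one-way ANOVA with clutch as
  factor; Storey q-values at FDR < 5% (BH available).
- **Enrichment.** Average-odds scanning of 3'UTR polyadenylation motifs
  (AAUAAA/AUUAAA, CPEs, PBE, 11–20-nt poly-U embryonic CPEs) with
  one-sided rank-sum tests and Bonferroni correction; hypergeometric
  gene-set overrepresentation; cluster × chromosome fraction matrices
  with Euclidean/Ward clustering.
- **A synthetic-data generator** that emulates the design (24 eggs in
  five clutches, bimodal probe population, mother-level offsets, per-array
  scaling, multiple probes per gene) and records ground truth, so every
  step is testable without the original arrays.

## Worked example

```r
library(clutchsig)

d <- generate_dataset(sim_config(n_genes = 1000, seed = 11,
                                 n_native_probes = 20))
m <- quantile_normalize(d$matrix)
res <- call_expressed_genes(m, d$annotation)
res$valley
#> [1] -3.591983
length(res$expressed_genes)
#> [1] 348

gm <- gene_matrix(m, res$representative_probe, res$expressed_genes)
cl <- clutch_factor(m)
mfc_summary(mfc_table(gm, cl), thresholds = c(2, 4))
#>   threshold frac_experiment frac_within_clutch
#> 1         2       0.3534483          0.8735632
#> 2         4       0.8074713          1.0000000

prof <- profile_genes(gm, cl)
head(group_clusters(prof, min_size = 5)[, c("code", "n_genes")])
de <- diffexp_table(gm, cl, fdr = 0.05)
mean(de$significant)
#> [1] 0.704023
```

The valley near −3.6 splits low- from high-variance probes; 348 of 1,000
genes are called expressed (truth planted 340). About 87% of expressed
genes vary less than twofold *within* clutches while only ~33% do so
across all 24 eggs — the variability is mother-driven — and ~70% of
expressed genes are differential between clutches at FDR 5% under the
generator's default (mild) clutch jitter.

## Analysis workflow

`analysis/` holds the pipeline as numbered drivers, each a thin narrative
over package functions, writing tables under `results/data/`:

```sh
Rscript analysis/01_simulate.R        # synthetic 24-egg study + truth
Rscript analysis/02_preprocess.R      # extreme genes, suspect probes, normalization
Rscript analysis/03_expression_call.R # valley, posteriors, gene calls
Rscript analysis/04_variability.R     # mFC tables and threshold fractions
Rscript analysis/05_signature.R       # profile codes, clusters, inverse pairs
Rscript analysis/06_diffexp.R         # per-gene ANOVA + q-values
Rscript analysis/07_enrichment.R      # UTR motifs, miRNA targets, chromosomes
```

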