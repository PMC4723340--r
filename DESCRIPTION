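Package: clutchsig
Title: Mother-Specific Signatures in Single-Egg Maternal Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for probe-level microarray intensities from
    individual unfertilized eggs sampled in clutches from several mothers.
    Provides quality filtering and quantile normalization, expressed-gene
    calling from the bimodality of per-probe intensity variance with
    per-array Bayes posteriors, maximum fold-change variability statistics
    experiment-wide and within clutches, detection of genes with absolutely
    distinct per-clutch expression levels and their grouping into
    mother-specific signature clusters, per-gene one-way ANOVA with
    q-value false-discovery-rate control, 3'UTR sequence-motif enrichment,
    hypergeometric gene-set overrepresentation, and chromosome-distribution
    clustering. A synthetic-data generator with ground truth emulates the
    clutch design so every step is testable without the original arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
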