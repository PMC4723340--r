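#' Remove genes with a single extreme outlier sample
#'
#' A gene is removed when exactly one sample sits at least
#' `log2(fc_threshold)` above the maximum of all its other samples —
#' the pattern of one unrealistically high value against an otherwise
#' absent signal. Evaluated on the gene's representative intensity per
#' probe and aggregated per gene: a gene is flagged if any of its probes
#' shows the pattern.
#'
#' @param m a [probe_matrix()]
#' @param annotation data.frame with `probe_id`, `gene_id`
#' @param fc_threshold linear fold-change threshold, > 1 (default 3000)
#' @return list: `matrix` (filtered), `report` (QC data.frame of removed
#'   genes with the triggering probe and observed log2 gap)
#' @export
remove_extreme_genes <- function(m, annotation, fc_threshold = 3000) {
  stopifnot(fc_threshold > 1)
  v <- m$values
  n <- ncol(v)
  if (n < 2) stop("need >= 2 samples")
  cut <- log2(fc_threshold)
  # gap between the top value and the runner-up, per probe
  top2 <- t(apply(v, 1, function(x) sort(x, decreasing = TRUE)[1:2]))
  gap <- top2[, 1] - top2[, 2]
  flagged <- which(gap >= cut)
  probes <- rownames(v)[flagged]
  gene_of <- stats::setNames(annotation$gene_id, annotation$probe_id)
  bad_genes <- unique(unname(gene_of[probes]))
  bad_genes <- bad_genes[!is.na(bad_genes)]
  report <- data.frame(gene_id = unname(gene_of[probes]),
                       probe_id = probes,
                       log2_gap = unname(gap[flagged]),
                       stringsAsFactors = FALSE)
  report <- report[!is.na(report$gene_id), , drop = FALSE]
  keep <- !(gene_of[rownames(v)] %in% bad_genes)
  keep[is.na(keep)] <- TRUE   # probes without annotation are retained
  list(matrix = set_values(m, v[keep, , drop = FALSE]), report = report)
}

#' Flag probes anti-correlated with the array scaling factors
#'
#' Raw intensities are centered on the array average; the per-array
#' scaling factor is that array average minus the grand average. Probes
#' whose centered intensities strongly anti-correlate with the scaling
#' factors while varying substantially are flagged: their signal does not
#' follow the array scale, the hallmark of transcripts carrying native
#' long poly(A) tails whose intensities between-array normalization would
#' distort rather than fix.
#'
#' @param m a raw (pre-normalization) [probe_matrix()]
#' @param corr_cut flag when correlation <= this (default -0.8)
#' @param sd_cut flag when centered sd >= this; default the 90th
#'   percentile of the centered sds
#' @return data.frame per probe: `probe_id`, `anti_correlation`,
#'   `centered_sd`, `suspect`
#' @export
detect_suspect_probes <- function(m, corr_cut = -0.8, sd_cut = NULL) {
  v <- m$values
  if (ncol(v) < 3) stop("need >= 3 samples for correlation statistics")
  array_avg <- colMeans(v)
  scaling <- array_avg - mean(array_avg)
  centered <- sweep(v, 2, array_avg, "-")
  sds <- apply(centered, 1, stats::sd)
  cors <- suppressWarnings(as.vector(stats::cor(t(centered), scaling)))
  cors[is.na(cors)] <- 0      # constant probes: no direction, never flagged
  if (is.null(sd_cut)) sd_cut <- stats::quantile(sds, 0.9, names = FALSE)
  data.frame(probe_id = rownames(v),
             anti_correlation = cors,
             centered_sd = sds,
             suspect = cors <= corr_cut & sds >= sd_cut,
             stringsAsFactors = FALSE)
}

#' Drop probes flagged by [detect_suspect_probes()]
#' @param m a [probe_matrix()]
#' @param report output of [detect_suspect_probes()]
#' @return filtered `probe_matrix`
#' @export
drop_suspect_probes <- function(m, report) {
  bad <- report$probe_id[report$suspect]
  set_values(m, m$values[!rownames(m$values) %in% bad, , drop = FALSE])
}

#' Quantile normalization between arrays
#'
#' Each column's sorted values are replaced by the across-column mean of
#' sorted values; within-column ranks are preserved, and ties receive the
#' mean of their tied quantile values.
#'
#' @param m a [probe_matrix()]
#' @return normalized `probe_matrix`
#' @export
quantile_normalize <- function(m) {
  set_values(m, limma::normalizeQuantiles(m$values, ties = TRUE))
}
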