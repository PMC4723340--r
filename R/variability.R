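#' Experiment-wide maximum fold change per gene
#'
#' Per gene (row), the log2 maximum fold change over all samples:
#' max(log2 intensity) - min(log2 intensity).
#'
#' @param values numeric vector (one gene) or genes x samples matrix of
#'   log2 intensities
#' @return log2 mFC, scalar or named vector
#' @export
max_fold_change <- function(values) {
  if (is.matrix(values)) {
    if (ncol(values) < 2) stop("need >= 2 samples")
    apply(values, 1, function(x) max(x) - min(x))
  } else {
    if (length(values) < 2) stop("need >= 2 samples")
    max(values) - min(values)
  }
}

#' Within-clutch maximum fold change per gene
#'
#' The largest, over clutches, of the difference between the highest and
#' lowest log2 intensity within the same clutch.
#'
#' @param values numeric vector or genes x samples matrix
#' @param clutch factor/vector of clutch ids, one per sample
#' @return log2 within-clutch mFC, scalar or named vector
#' @export
within_clutch_mfc <- function(values, clutch) {
  clutch <- as.factor(clutch)
  if (any(table(clutch) < 2))
    stop("every clutch needs >= 2 samples (range undefined for singletons)")
  one <- function(x) {
    rng <- tapply(x, clutch, function(v) max(v) - min(v))
    max(rng)
  }
  if (is.matrix(values)) apply(values, 1, one) else one(values)
}

#' Per-gene fold-change variability table
#'
#' @param gm genes x samples matrix of log2 intensities (typically from
#'   [gene_matrix()] on expressed genes)
#' @param clutch clutch assignment, one entry per column
#' @return data.frame per gene: `mfc_experiment`, `mfc_within_clutch`, and
#'   per-clutch min/max/mean log2 intensity columns
#' @export
mfc_table <- function(gm, clutch) {
  clutch <- as.factor(clutch)
  out <- data.frame(gene_id = rownames(gm),
                    mfc_experiment = max_fold_change(gm),
                    mfc_within_clutch = within_clutch_mfc(gm, clutch),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (cl in levels(clutch)) {
    sub <- gm[, clutch == cl, drop = FALSE]
    out[[paste0("min_", cl)]] <- apply(sub, 1, min)
    out[[paste0("max_", cl)]] <- apply(sub, 1, max)
    out[[paste0("mean_", cl)]] <- rowMeans(sub)
  }
  out
}

#' Fractions of genes below fold-change thresholds
#'
#' Thresholds are linear fold changes applied as log2 bounds with `<=`
#' (a gene with mFC exactly 2 counts in the "mFC <= 2" bucket).
#'
#' @param table output of [mfc_table()]
#' @param thresholds linear FC thresholds, all > 1 (default c(2, 4))
#' @return data.frame: `threshold`, `frac_experiment`, `frac_within_clutch`
#' @export
mfc_summary <- function(table, thresholds = c(2, 4)) {
  stopifnot(all(thresholds > 1))
  data.frame(threshold = thresholds,
             frac_experiment = vapply(thresholds, function(t)
               mean(table$mfc_experiment <= log2(t)), numeric(1)),
             frac_within_clutch = vapply(thresholds, function(t)
               mean(table$mfc_within_clutch <= log2(t)), numeric(1)))
}
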