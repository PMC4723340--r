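#' Built-in 3'UTR regulatory motif set
#'
#' The motifs implicated in cytoplasmic polyadenylation of stored maternal
#' transcripts: the polyadenylation hexamers AAUAAA and AUUAAA, the U-rich
#' cytoplasmic polyadenylation elements UUUUAU and UUUUAMU, the Pumilio
#' binding element UGUA(N)AUA, and the embryonic CPEs — uninterrupted U
#' runs of length 11 to 20, each a separate motif in the multiple-testing
#' family.
#'
#' @return named character vector of IUPAC patterns over the RNA alphabet
#' @export
builtin_motifs <- function() {
  ecpe <- vapply(11:20, function(k) strrep("U", k), character(1))
  names(ecpe) <- paste0("eCPE_U", 11:20)
  c(PAS_AAUAAA = "AAUAAA", PAS_AUUAAA = "AUUAAA",
    CPE_UUUUAU = "UUUUAU", CPE_UUUUAMU = "UUUUAMU",
    PBE_UGUANAUA = "UGUANAUA", ecpe)
}

# IUPAC (RNA) -> allowed bases
iupac_rna <- list(A = "A", C = "C", G = "G", U = "U",
                  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
                  W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
                  B = c("C", "G", "U"), D = c("A", "G", "U"),
                  H = c("A", "C", "U"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "U"))

#' Consensus sequence of an IUPAC pattern
#'
#' Ambiguous positions are resolved to their first allowed base in
#' alphabetical order (M -> A, N -> A); used when planting exact motif
#' occurrences in synthetic UTRs.
#'
#' @param pattern IUPAC string over the RNA alphabet (T accepted as U)
#' @return unambiguous RNA string
#' @export
motif_consensus <- function(pattern) {
  letters_ <- strsplit(chartr("Tt", "Uu", toupper(pattern)), "")[[1]]
  bad <- !letters_ %in% names(iupac_rna)
  if (any(bad)) stop("invalid IUPAC letter(s): ",
                     paste(unique(letters_[bad]), collapse = ", "))
  paste(vapply(letters_, function(l) iupac_rna[[l]][1], character(1)),
        collapse = "")
}

#' Average-odds motif score of a sequence
#'
#' The IUPAC pattern is read as a position-weight model with probability
#' `1/|allowed bases|` on each allowed base and a uniform 0.25 background.
#' Every window on the given strand is scored by the odds product
#' `prod_j p(base_j | motif) / 0.25`; the sequence score is the average
#' over all windows. An exact-match count (windows where every position is
#' an allowed base) is attached as attribute `n_matches`. A sequence
#' shorter than the motif scores 0 with attribute `too_short = TRUE`.
#' `N` in the sequence matches only all-N motif columns.
#'
#' @param sequence RNA string (DNA input is mapped T -> U)
#' @param pattern IUPAC motif
#' @return average odds score (scalar) with attributes `n_matches`,
#'   `too_short`
#' @export
scan_motif <- function(sequence, pattern) {
  seq_chars <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  pat_chars <- strsplit(chartr("Tt", "Uu", toupper(pattern)), "")[[1]]
  if (!length(pat_chars)) stop("empty motif")
  w <- length(pat_chars)
  L <- length(seq_chars)
  if (L < w)
    return(structure(0, n_matches = 0L, too_short = TRUE))
  bases <- c("A", "C", "G", "U")
  seq_idx <- match(seq_chars, bases)          # N and others -> NA
  # odds factor per motif column x base (5th column = non-ACGU in sequence)
  fac <- matrix(0, w, 5)
  for (j in seq_len(w)) {
    allowed <- iupac_rna[[pat_chars[j]]]
    if (is.null(allowed)) stop("invalid IUPAC letter: ", pat_chars[j])
    fac[j, match(allowed, bases)] <- (1 / length(allowed)) / 0.25
    if (length(allowed) == 4) fac[j, 5] <- 1   # N column matches anything
  }
  seq_idx[is.na(seq_idx)] <- 5L
  n_win <- L - w + 1L
  odds <- rep(1, n_win)
  for (j in seq_len(w))
    odds <- odds * fac[j, seq_idx[seq(j, j + n_win - 1L)]]
  structure(mean(odds), n_matches = sum(odds > 0), too_short = FALSE)
}

#' Discriminative motif enrichment by rank-sum test
#'
#' Scores every sequence with [scan_motif()] and tests, per motif, whether
#' foreground scores exceed control scores (one-sided Wilcoxon rank-sum),
#' Bonferroni-correcting across the motif set. Matches a discriminative
#' setup in which the control group holds all sequences of the comparison
#' outside the set of interest, scanning one strand only.
#'
#' @param foreground named character vector of RNA sequences
#' @param control named character vector of RNA sequences
#' @param motifs named character vector of IUPAC patterns
#'   (default [builtin_motifs()])
#' @return data.frame per motif: `motif_id`, `pattern`, `w_statistic`,
#'   `p_raw`, `p_adjusted` (Bonferroni, capped at 1), `n_foreground`,
#'   `n_control`
#' @export
motif_enrichment <- function(foreground, control, motifs = builtin_motifs()) {
  if (!length(foreground) || !length(control))
    stop("foreground and control must both be non-empty")
  n_m <- length(motifs)
  rows <- lapply(seq_len(n_m), function(i) {
    fg <- vapply(foreground, scan_motif, numeric(1), pattern = motifs[i])
    ct <- vapply(control, scan_motif, numeric(1), pattern = motifs[i])
    if (length(unique(c(fg, ct))) == 1L) {
      p <- 1; w <- NA_real_
    } else {
      ht <- suppressWarnings(
        stats::wilcox.test(fg, ct, alternative = "greater", exact = FALSE))
      p <- ht$p.value; w <- unname(ht$statistic)
    }
    data.frame(motif_id = names(motifs)[i], pattern = unname(motifs[i]),
               w_statistic = w, p_raw = p,
               n_foreground = length(fg), n_control = length(ct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * n_m)
  out[, c("motif_id", "pattern", "w_statistic", "p_raw", "p_adjusted",
          "n_foreground", "n_control")]
}

#' Hypergeometric overrepresentation of a gene set
#'
#' Upper-tail hypergeometric probability of seeing at least the observed
#' overlap between a set of interest and an annotation set, both drawn
#' from a finite universe (the genes represented on the array, or the
#' expressed genes, depending on the comparison).
#'
#' @param set_of_interest gene ids
#' @param annotation_set gene ids (e.g. targets of one miRNA)
#' @param universe background gene ids; both sets are intersected with it
#' @return list: `overlap`, `p_value`, `n_interest`, `n_annotation`,
#'   `n_universe`
#' @export
hypergeom_overrep <- function(set_of_interest, annotation_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  interest <- unique(intersect(set_of_interest, universe))
  ann <- unique(intersect(annotation_set, universe))
  k <- length(intersect(interest, ann))
  p <- stats::phyper(k - 1, length(ann), length(universe) - length(ann),
                     length(interest), lower.tail = FALSE)
  list(overlap = k, p_value = p,
       n_interest = length(interest), n_annotation = length(ann),
       n_universe = length(universe))
}

#' Overlap of a gene set with a reference study's set
#'
#' The fraction of the reference set recovered:
#' `|ours intersect reference| / |reference|`.
#'
#' @param our_set gene ids
#' @param reference_set gene ids from the external study
#' @return fraction in `[0, 1]`
#' @export
gene_set_overlap <- function(our_set, reference_set) {
  if (!length(reference_set)) stop("empty reference set")
  length(intersect(unique(our_set), unique(reference_set))) /
    length(unique(reference_set))
}

#' Cluster x chromosome fraction matrix
#'
#' For each gene cluster, the fraction of its genes located on each
#' chromosome; rows sum to 1. Genes without a chromosome assignment are
#' counted in an `unplaced` column. Empty clusters are dropped with a
#' message.
#'
#' @param clusters named list of gene-id vectors (e.g. from the `genes`
#'   column of [group_clusters()], named by code)
#' @param gene2chrom named character vector gene id -> chromosome
#' @return numeric matrix, clusters x chromosomes
#' @export
chromosome_fraction_matrix <- function(clusters, gene2chrom) {
  empty <- lengths(clusters) == 0
  if (any(empty)) {
    message(sum(empty), " empty cluster(s) dropped")
    clusters <- clusters[!empty]
  }
  if (!length(clusters)) stop("no non-empty clusters")
  chroms <- sort(unique(unname(gene2chrom)))
  cols <- c(chroms, "unplaced")
  out <- t(vapply(clusters, function(genes) {
    ch <- unname(gene2chrom[genes])
    ch[is.na(ch)] <- "unplaced"
    as.vector(table(factor(ch, levels = cols))) / length(genes)
  }, numeric(length(cols))))
  colnames(out) <- cols
  if (all(out[, "unplaced"] == 0))
    out <- out[, chroms, drop = FALSE]
  out
}

#' Hierarchical clustering of matrix rows (Euclidean, Ward linkage)
#'
#' Agglomerative clustering with Euclidean distance and Ward's linkage.
#' Also reports which pairs of rows merge as two singletons (mutual
#' nearest neighbours at merge time) and, when row names are profile
#' codes, which of those first merges join a code with its inverse.
#'
#' @param mat numeric matrix with >= 2 rows; no missing values
#' @return list: `hclust` (the tree), `order` (row names in dendrogram
#'   order), `singleton_pairs` (data.frame of rows merged as pairs),
#'   `inverse_pairs_merged` (subset where the pair is code/inverse-code)
#' @export
ward_cluster_rows <- function(mat) {
  if (nrow(mat) < 2) stop("need >= 2 rows")
  if (anyNA(mat)) stop("missing values in matrix")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  merges <- hc$merge
  singleton <- merges[, 1] < 0 & merges[, 2] < 0
  labs <- if (is.null(rownames(mat))) as.character(seq_len(nrow(mat))) else rownames(mat)
  pairs <- data.frame(row1 = labs[-merges[singleton, 1]],
                      row2 = labs[-merges[singleton, 2]],
                      height = hc$height[singleton],
                      stringsAsFactors = FALSE)
  inv <- pairs[!is.na(vapply(pairs$row1, inverse_code, character(1))) &
                 vapply(pairs$row1, inverse_code, character(1)) == pairs$row2,
               , drop = FALSE]
  list(hclust = hc, order = labs[hc$order],
       singleton_pairs = pairs, inverse_pairs_merged = inv)
}
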