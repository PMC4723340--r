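#' Per-probe log variance of log intensity
#'
#' Natural log of the unbiased sample variance of each probe's log2
#' intensities across all samples. Probes with zero variance get a finite
#' sentinel (the minimum finite log-variance minus 1) so downstream
#' thresholding stays well-defined; they always land in the low-variance
#' class.
#'
#' @param m a [probe_matrix()]
#' @return named numeric vector, probe id -> log variance
#' @export
probe_log_variance <- function(m) {
  v <- m$values
  if (ncol(v) < 2) stop("need >= 2 samples")
  vars <- apply(v, 1, stats::var)
  lv <- log(vars)
  if (any(!is.finite(lv))) {
    fin <- lv[is.finite(lv)]
    sentinel <- if (length(fin)) min(fin) - 1 else -1
    lv[!is.finite(lv)] <- sentinel
  }
  stats::setNames(lv, rownames(v))
}

#' Locate the valley between the two modes of a bimodal distribution
#'
#' A kernel density estimate (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth) is evaluated on a fine grid; local maxima are collected, and
#' the valley is the grid point of minimum density strictly between the
#' two highest modes. Unimodal input is an error — no silent threshold is
#' produced.
#'
#' @param log_variances numeric vector (e.g. from [probe_log_variance()])
#' @param n_grid density grid size (default 512)
#' @param bw bandwidth passed to [stats::density()] (default "nrd0",
#'   Silverman's rule)
#' @param min_mode_frac local maxima below this fraction of the global
#'   density maximum are ignored as wiggles (default 0.05)
#' @return the valley location (scalar)
#' @export
find_valley_threshold <- function(log_variances, n_grid = 512,
                                  bw = "nrd0", min_mode_frac = 0.05) {
  x <- log_variances[is.finite(log_variances)]
  if (length(x) < 10) stop("too few values for density estimation")
  d <- stats::density(x, bw = bw, n = n_grid)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  is_max <- is_max[y[is_max] >= min_mode_frac * max(y)]
  if (length(is_max) < 2)
    stop("distribution is not bimodal: fewer than two modes detected")
  top2 <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- seq(lo, hi)
  valley_idx <- between[which.min(y[between])]
  d$x[valley_idx]
}

#' Partition probes into low- and high-variance classes
#'
#' Probes with log variance strictly below the valley are "low variance"
#' (non-expressed population); probes at or above the valley are "high
#' variance". The boundary convention (valley itself -> high) is fixed and
#' tested.
#'
#' @param log_variances named numeric vector
#' @param valley threshold from [find_valley_threshold()]
#' @return list of class `variance_split`: `log_variance`, `valley`,
#'   `low_probes`, `high_probes`
#' @export
classify_probe_variance <- function(log_variances, valley) {
  if (!is.finite(valley)) stop("valley must be finite")
  high <- log_variances >= valley
  structure(list(log_variance = log_variances,
                 valley = valley,
                 low_probes = names(log_variances)[!high],
                 high_probes = names(log_variances)[high]),
            class = "variance_split")
}

#' Per-array posterior probability that a probe is expressed
#'
#' For each array separately, class-conditional intensity densities are
#' estimated by Gaussian kernel density (or a two-Gaussian fit) from that
#' array's low-class and high-class probe intensities. The posterior for
#' probe intensity x is
#' `pi_high * f_high(x) / (pi_high * f_high(x) + pi_low * f_low(x))`
#' with priors equal to the experiment-wide class proportions. Outside the
#' joint support of both densities the posterior is extended from the
#' nearest supported intensity (nearest-support extrapolation).
#'
#' @param m a [probe_matrix()]
#' @param split a `variance_split` from [classify_probe_variance()]
#' @param density_model "kde" (default) or "gaussian" (two-Gaussian fit)
#' @return probe x sample matrix of posteriors in `[0, 1]`
#' @export
posterior_expressed <- function(m, split, density_model = c("kde", "gaussian")) {
  density_model <- match.arg(density_model)
  v <- m$values
  low <- rownames(v) %in% split$low_probes
  high <- rownames(v) %in% split$high_probes
  if (!any(low) || !any(high))
    stop("both variance classes must be non-empty")
  pi_high <- sum(high) / (sum(high) + sum(low))
  pi_low <- 1 - pi_high
  post <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    if (density_model == "kde") {
      f_low <- kde_at(x[low], x)
      f_high <- kde_at(x[high], x)
    } else {
      f_low <- stats::dnorm(x, mean(x[low]), stats::sd(x[low]))
      f_high <- stats::dnorm(x, mean(x[high]), stats::sd(x[high]))
    }
    num <- pi_high * f_high
    den <- num + pi_low * f_low
    p <- ifelse(den > 0, num / den, NA_real_)
    # nearest-support extrapolation where both densities vanish
    if (anyNA(p)) {
      ok <- which(!is.na(p))
      ord <- order(x)
      p_ord <- p[ord]
      filled <- stats::approx(x = x[ord][!is.na(p_ord)],
                              y = p_ord[!is.na(p_ord)],
                              xout = x, method = "constant",
                              rule = 2, ties = "ordered")$y
      p[is.na(p)] <- filled[is.na(p)]
    }
    post[, j] <- p
  }
  post
}

# KDE from `train`, evaluated at `at` by linear interpolation on a grid
# padded past the data range; density 0 far outside the support.
kde_at <- function(train, at) {
  if (length(unique(train)) < 2) {
    # degenerate class: point mass smeared with a token bandwidth
    return(stats::dnorm(at, mean(train), 1e-3))
  }
  d <- stats::density(train, n = 1024, cut = 4)
  y <- stats::approx(d$x, d$y, xout = at, rule = 1)$y
  y[is.na(y)] <- 0
  pmax(y, 0)
}

#' Call expressed transcripts from per-sample probe calls
#'
#' A transcript is "expressed somewhere in the experiment" when its probe
#' is called expressed (posterior above threshold) on at least
#' `min_arrays` arrays.
#'
#' @param posterior probe x sample posterior matrix
#' @param annotation data.frame with `probe_id`, `transcript_id`
#' @param posterior_threshold call cutoff (default 0.95, strict `>`)
#' @param min_arrays minimum number of arrays (default 4)
#' @return list: `expressed_transcripts` (character), `probe_calls`
#'   (logical matrix), `n_arrays_expressed` (named count per probe),
#'   `unprobed_transcripts` (annotation rows without a probe in the matrix)
#' @export
call_transcripts <- function(posterior, annotation,
                             posterior_threshold = 0.95, min_arrays = 4) {
  stopifnot(min_arrays >= 1)
  calls <- posterior > posterior_threshold
  n_expr <- rowSums(calls)
  probe2tx <- stats::setNames(annotation$transcript_id, annotation$probe_id)
  known <- names(n_expr)[names(n_expr) %in% names(probe2tx)]
  expressed_probes <- known[n_expr[known] >= min_arrays]
  missing <- setdiff(annotation$probe_id, rownames(posterior))
  list(expressed_transcripts = unname(probe2tx[expressed_probes]),
       probe_calls = calls,
       n_arrays_expressed = n_expr,
       unprobed_transcripts = unname(probe2tx[missing]))
}

#' Collapse transcript calls to gene calls and pick representative probes
#'
#' A gene is expressed when at least one of its transcripts is expressed.
#' Per gene the representative probe is the one with the highest mean
#' intensity over all samples (ties: lexicographically smallest probe id).
#'
#' @param expressed_transcripts character vector from [call_transcripts()]
#' @param annotation data.frame with `probe_id`, `transcript_id`, `gene_id`
#' @param m the (normalized) [probe_matrix()]
#' @return list: `expressed_genes`, `nonexpressed_genes`,
#'   `representative_probe` (named: gene -> probe), `gene_mean_intensity`
#' @export
collapse_genes <- function(expressed_transcripts, annotation, m) {
  ann <- annotation[annotation$probe_id %in% rownames(m$values), , drop = FALSE]
  dropped <- setdiff(unique(annotation$gene_id), unique(ann$gene_id))
  if (length(dropped))
    warning(length(dropped), " gene(s) with no probe in the matrix excluded")
  probe_mean <- rowMeans(m$values)[ann$probe_id]
  ord <- order(ann$gene_id, -probe_mean, ann$probe_id)
  first <- !duplicated(ann$gene_id[ord])
  rep_probe <- stats::setNames(ann$probe_id[ord][first], ann$gene_id[ord][first])
  expr_genes <- sort(unique(
    ann$gene_id[ann$transcript_id %in% expressed_transcripts]))
  all_genes <- sort(unique(ann$gene_id))
  list(expressed_genes = expr_genes,
       nonexpressed_genes = setdiff(all_genes, expr_genes),
       representative_probe = rep_probe,
       gene_mean_intensity = stats::setNames(
         unname(rowMeans(m$values)[rep_probe]), names(rep_probe)))
}

#' Full expressed-gene calling pipeline
#'
#' Convenience wrapper: log variance, valley detection, variance split,
#' per-array posteriors, transcript calls and gene collapse, on an
#' already-normalized matrix.
#'
#' @inheritParams posterior_expressed
#' @inheritParams call_transcripts
#' @param annotation probe annotation data.frame
#' @return list combining the outputs of the stages, plus `valley` and the
#'   `variance_split`
#' @export
call_expressed_genes <- function(m, annotation,
                                 posterior_threshold = 0.95, min_arrays = 4,
                                 density_model = "kde") {
  lv <- probe_log_variance(m)
  valley <- find_valley_threshold(lv)
  split <- classify_probe_variance(lv, valley)
  post <- posterior_expressed(m, split, density_model = density_model)
  tx <- call_transcripts(post, annotation,
                         posterior_threshold = posterior_threshold,
                         min_arrays = min_arrays)
  genes <- collapse_genes(tx$expressed_transcripts, annotation, m)
  c(list(valley = valley, variance_split = split, posterior = post), tx, genes)
}

#' Gene-level expression matrix on representative probes
#' @param m a [probe_matrix()]
#' @param representative_probe named vector gene -> probe id
#' @param genes gene ids to extract (default all in the map)
#' @return genes x samples matrix of log2 intensities
#' @export
gene_matrix <- function(m, representative_probe, genes = names(representative_probe)) {
  probes <- representative_probe[genes]
  out <- m$values[probes, , drop = FALSE]
  rownames(out) <- genes
  out
}
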