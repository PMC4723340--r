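#' One-way fixed-effects ANOVA F-test per gene, clutch as factor
#'
#' Standard one-way F statistic computed in closed form across all genes
#' at once (between-clutch mean square over within-clutch mean square),
#' with p-values from the F distribution on (k - 1, n - k) degrees of
#' freedom. Genes with zero within-clutch variance but non-zero
#' between-clutch variance get the smallest representable p and are
#' flagged.
#'
#' @param gm genes x samples matrix of log2 intensities
#' @param clutch clutch assignment per column (>= 2 clutches, each with
#'   >= 2 samples)
#' @return data.frame per gene: `gene_id`, `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `zero_within_var` flag
#' @export
anova_f_per_gene <- function(gm, clutch) {
  clutch <- as.factor(clutch)
  k <- nlevels(clutch)
  n <- ncol(gm)
  if (k < 2) stop("need >= 2 clutches")
  if (any(table(clutch) < 2)) stop("each clutch needs >= 2 samples")
  n_c <- as.vector(table(clutch))
  group_sum <- t(rowsum(t(gm), clutch))          # genes x clutches
  group_mean <- sweep(group_sum, 2, n_c, "/")
  grand_mean <- rowSums(group_sum) / n
  ssb <- rowSums(sweep((group_mean - grand_mean)^2, 2, n_c, "*"))
  sst <- rowSums((gm - grand_mean)^2)
  ssw <- pmax(sst - ssb, 0)
  df_b <- k - 1L
  df_w <- n - k
  f <- (ssb / df_b) / (ssw / df_w)
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  degenerate <- ssw == 0 & ssb > 0
  f[degenerate] <- Inf
  p[degenerate] <- .Machine$double.xmin
  data.frame(gene_id = rownames(gm),
             f_statistic = f,
             df_between = df_b, df_within = df_w,
             p_value = p,
             zero_within_var = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Storey q-values with smoother pi0 estimation
#'
#' The proportion of true nulls pi0 is estimated on a lambda grid
#' (default 0.05 to 0.95 by 0.05) as
#' `pi0(lambda) = #{p > lambda} / (m (1 - lambda))`, smoothed with a
#' cubic smoothing spline (3 df) and evaluated at the largest lambda,
#' clipped to (0, 1]. q-values are the monotone step-down
#' `q(i) = min_{j >= i} pi0 * m * p(j) / j` over p-value ranks. With
#' `method = "bh"`, Benjamini-Hochberg adjusted p-values are returned
#' instead (equivalent to forcing pi0 = 1).
#'
#' @param p_values numeric vector in `[0, 1]`
#' @param fdr significance cutoff on q (default 0.05)
#' @param method "storey" (default) or "bh"
#' @param lambda grid for pi0 estimation
#' @return list: `q_values`, `pi0`, `significant` (logical, q < fdr)
#' @export
estimate_qvalues <- function(p_values, fdr = 0.05,
                             method = c("storey", "bh"),
                             lambda = seq(0.05, 0.95, 0.05)) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  m <- length(p_values)
  if (method == "bh") {
    q <- stats::p.adjust(p_values, method = "BH")
    return(list(q_values = q, pi0 = 1, significant = q < fdr))
  }
  pi0_lambda <- vapply(lambda, function(l)
    mean(p_values > l) / (1 - l), numeric(1))
  if (all(pi0_lambda == 0)) {
    pi0 <- 1 / m   # every p tiny: effectively no nulls, keep pi0 positive
  } else {
    fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  ord <- order(p_values, decreasing = TRUE)
  q <- pi0 * m * p_values[ord] / rank(p_values, ties.method = "max")[ord]
  q <- pmin(cummin(pmin(q, 1)), 1)
  q_values <- numeric(m)
  q_values[ord] <- q
  list(q_values = q_values, pi0 = pi0, significant = q_values < fdr)
}

#' Per-gene differential-expression results at a stated FDR
#'
#' Runs [anova_f_per_gene()] and [estimate_qvalues()] and assembles the
#' standard result table.
#'
#' @inheritParams anova_f_per_gene
#' @inheritParams estimate_qvalues
#' @return data.frame per gene: F statistic, dfs, p, q, `significant`
#' @export
diffexp_table <- function(gm, clutch, fdr = 0.05, method = "storey") {
  res <- anova_f_per_gene(gm, clutch)
  qv <- estimate_qvalues(res$p_value, fdr = fdr, method = method)
  res$q_value <- qv$q_values
  res$significant <- qv$significant
  attr(res, "pi0") <- qv$pi0
  res
}
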