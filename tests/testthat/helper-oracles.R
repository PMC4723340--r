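# Independent brute-force oracles used across the suite. These stay
# straight-line and naive on purpose: they must not share code paths with
# the implementation they check.

# All set partitions of 1..n as lists of integer vectors
all_set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- all_set_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Finest partition of clutch intervals into groups with pairwise strictly
# disjoint hulls (closed-interval overlap convention)
brute_force_levels <- function(lo, hi) {
  k <- length(lo)
  best <- NULL
  for (p in all_set_partitions(k)) {
    hulls <- lapply(p, function(g) c(min(lo[g]), max(hi[g])))
    ok <- TRUE
    if (length(p) > 1) {
      for (i in seq_along(p)[-1]) for (j in seq_len(i - 1)) {
        a <- hulls[[i]]; b <- hulls[[j]]
        if (a[1] <= b[2] && b[1] <= a[2]) { ok <- FALSE; break }
      }
    }
    if (ok && (is.null(best) || length(p) > length(best))) best <- p
  }
  best
}

# canonical form of a partition for set comparison
canon_partition <- function(p) {
  sets <- lapply(p, function(g) sort(as.integer(g)))
  unname(sets[order(vapply(sets, min, integer(1)))])
}

# exact upper-tail hypergeometric by enumeration over all overlap outcomes
brute_force_hyper <- function(k_obs, n_ann, n_universe, n_draw) {
  ks <- 0:min(n_ann, n_draw)
  probs <- choose(n_ann, ks) * choose(n_universe - n_ann, n_draw - ks) /
    choose(n_universe, n_draw)
  sum(probs[ks >= k_obs])
}

# toy bimodal dataset for the straight-line pipeline oracle:
# 10 near-constant background probes and 10 variable expressed probes,
# 2 probes per gene, 6 samples in 3 clutches of 2
toy_bimodal_dataset <- function(seed = 404) {
  set.seed(seed)
  n_low <- 10; n_high <- 10
  probes <- sprintf("p%02d", 1:20)
  samples <- paste0("s", 1:6)
  vals <- rbind(
    matrix(rnorm(n_low * 6, 4, 0.05), n_low),
    matrix(rnorm(n_high * 6, rep(seq(8, 12, length.out = n_high), 6), 0.8),
           n_high))
  dimnames(vals) <- list(probes, samples)
  meta <- setNames(rep(c("A", "B", "C"), each = 2), samples)
  ann <- data.frame(probe_id = probes,
                    transcript_id = sub("p", "t", probes),
                    gene_id = rep(sprintf("g%02d", 1:10), each = 2),
                    chromosome = "chr1", stringsAsFactors = FALSE)
  list(m = probe_matrix(vals, meta), annotation = ann)
}
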