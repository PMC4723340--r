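test_that("motif scanning counts exact matches and scores identity motifs", {
  s <- scan_motif("AAAUAAA", "AAUAAA")
  expect_equal(attr(s, "n_matches"), 1L)          # offset 2, 1-based
  expect_gt(as.numeric(s), 0)
  # all-N motif: every window odds 1, average 1
  expect_equal(as.numeric(scan_motif("ACGUACGU", "NNNN")), 1)
  # shorter than motif -> 0, flagged
  short <- scan_motif("ACG", "AAUAAA")
  expect_equal(as.numeric(short), 0)
  expect_true(attr(short, "too_short"))
  # DNA input accepted
  expect_equal(attr(scan_motif("AATAAA", "AAUAAA"), "n_matches"), 1L)
  # ambiguity codes: M = A/C
  expect_equal(attr(scan_motif("UUUUAAU", "UUUUAMU"), "n_matches"), 1L)
  expect_equal(attr(scan_motif("UUUUACU", "UUUUAMU"), "n_matches"), 1L)
  expect_equal(attr(scan_motif("UUUUAGU", "UUUUAMU"), "n_matches"), 0L)
})

test_that("the built-in motif family is complete and well-formed", {
  mot <- builtin_motifs()
  expect_length(mot, 15)                   # 5 elements + 10 poly-U lengths
  expect_equal(unname(nchar(mot[paste0("eCPE_U", 11:20)])), 11:20)
  expect_identical(motif_consensus("UGUANAUA"), "UGUAAAUA")
  expect_identical(motif_consensus("UUUUAMU"), "UUUUAAU")
})

test_that("expected window odds is exactly 1 over the full sequence space", {
  # E[odds] = sum over windows of p(window) * prod p(base|motif)/0.25 = 1;
  # verified by complete enumeration of all 3-mers
  all3 <- apply(expand.grid(rep(list(c("A", "C", "G", "U")), 3)), 1,
                paste, collapse = "")
  for (pat in c("AAA", "AMU", "NNN", "UGC")) {
    scores <- vapply(all3, function(s) as.numeric(scan_motif(s, pat)),
                     numeric(1))
    expect_equal(mean(scores), 1, tolerance = 1e-12)
  }
})

test_that("motif enrichment separates planted from unplanted motifs", {
  genes_fg <- sprintf("fg%03d", 1:120)
  genes_ct <- sprintf("ct%03d", 1:120)
  planted <- list(AAUAAA = genes_fg[1:96])          # 80% of the foreground
  fg <- generate_utrs(genes_fg, planted, length = 200, seed = 15)
  ct <- generate_utrs(genes_ct, list(), length = 200, seed = 16)
  res <- motif_enrichment(fg, ct)
  expect_lt(res$p_adjusted[res$motif_id == "PAS_AAUAAA"], 1e-6)
  # no other motif should reach significance
  expect_true(all(res$p_adjusted[res$motif_id != "PAS_AAUAAA"] > 0.05))
  # foreground = control -> exchangeable, p near 1
  null_res <- motif_enrichment(fg, fg)
  expect_true(all(null_res$p_raw > 0.4))
  # single-motif family: Bonferroni factor 1
  one <- motif_enrichment(fg, ct, motifs = c(PAS_AAUAAA = "AAUAAA"))
  expect_equal(one$p_adjusted, one$p_raw)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("hypergeometric overrepresentation equals exact enumeration", {
  universe <- paste0("g", 1:10)
  res <- hypergeom_overrep(paste0("g", 1:4), paste0("g", c(1:4, 9)), universe)
  expect_equal(res$overlap, 4)
  expect_equal(res$p_value, 5 / 210)     # C(5,4)C(5,0)/C(10,4)
  # overlap 0 -> upper tail includes the observed case, p = 1
  res0 <- hypergeom_overrep("g1", "g2", universe)
  expect_equal(res0$p_value, 1)
  # interest = universe -> overlap forced to |annotation|, p = 1
  resU <- hypergeom_overrep(universe, paste0("g", 1:3), universe)
  expect_equal(resU$p_value, 1)
  expect_error(hypergeom_overrep("g1", "g2", character(0)), "empty universe")

  # randomized agreement with brute-force enumeration, universes <= 20
  set.seed(151)
  for (i in 1:200) {
    N <- sample(3:20, 1)
    uni <- paste0("u", 1:N)
    interest <- sample(uni, sample(N, 1))
    ann <- sample(uni, sample(N, 1))
    got <- hypergeom_overrep(interest, ann, uni)
    want <- brute_force_hyper(got$overlap, length(ann), N, length(interest))
    expect_equal(got$p_value, want, tolerance = 1e-12)
  }
})

test_that("gene-set overlap is the recovered fraction of the reference", {
  expect_equal(gene_set_overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(gene_set_overlap(c("a", "b"), c("x", "y")), 0)
  expect_equal(gene_set_overlap(c("a", "b", "c"), c("b", "c", "d", "e")), 0.5)
  expect_error(gene_set_overlap("a", character(0)), "empty reference")
})

test_that("chromosome fraction rows are exact fractions summing to one", {
  g2c <- setNames(c("chr1", "chr1", "chr2", "chr3", "chr1"),
                  paste0("g", 1:5))
  mat <- chromosome_fraction_matrix(
    list(c1 = paste0("g", 1:4), c2 = "g5"), g2c)
  expect_equal(mat["c1", c("chr1", "chr2", "chr3")], c(chr1 = 0.5, chr2 = 0.25, chr3 = 0.25))
  expect_equal(unname(mat["c2", "chr1"]), 1)
  expect_lt(max(abs(rowSums(mat) - 1)), 1e-12)
  # unmapped genes land in "unplaced"
  mat2 <- chromosome_fraction_matrix(list(c1 = c("g1", "gX")), g2c)
  expect_equal(unname(mat2["c1", "unplaced"]), 0.5)
  expect_message(chromosome_fraction_matrix(
    list(c1 = "g1", c2 = character(0)), g2c), "empty cluster")

  # large random cluster approaches the chromosome proportions
  set.seed(161)
  chroms <- paste0("chr", 1:25)
  g2c_big <- setNames(sample(chroms, 2000, replace = TRUE),
                      paste0("g", 1:2000))
  m3 <- chromosome_fraction_matrix(list(all = names(g2c_big)), g2c_big)
  expect_equal(unname(m3["all", chroms]),
               unname(table(factor(g2c_big, chroms)) / 2000),
               ignore_attr = TRUE)
})

test_that("Ward clustering merges planted inverse-profile pairs first", {
  set.seed(171)
  base <- matrix(runif(8 * 10), 8, 10)
  mat <- rbind(base, base + matrix(rnorm(80, 0, 1e-4), 8, 10))
  codes <- c("12222", "21222", "22122", "22212", "22221", "11222", "11122", "12122")
  rownames(mat) <- c(codes, vapply(codes, inverse_code, character(1)))
  res <- ward_cluster_rows(mat)
  expect_equal(nrow(res$inverse_pairs_merged), 8)

  # identical rows merge at height 0
  two <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  r2 <- ward_cluster_rows(two)
  expect_equal(r2$singleton_pairs$height[1], 0)
  expect_setequal(unlist(r2$singleton_pairs[1, 1:2]), c("a", "b"))

  # permuting rows leaves the tree topology unchanged
  perm <- sample(nrow(mat))
  res_p <- ward_cluster_rows(mat[perm, ])
  cut_a <- cutree(res$hclust, k = 8)
  cut_b <- cutree(res_p$hclust, k = 8)
  grp_a <- canon_partition(split(seq_len(16), cut_a[rownames(mat)]))
  grp_b <- canon_partition(split(seq_len(16), cut_b[rownames(mat)]))
  expect_identical(grp_a, grp_b)
  expect_error(ward_cluster_rows(rbind(c(1, NA), c(2, 3))), "missing values")
})
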