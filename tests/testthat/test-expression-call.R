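pm_of <- function(vals, mothers) {
  probe_matrix(vals, setNames(rep_len(mothers, ncol(vals)), colnames(vals)))
}

test_that("probe log variance matches hand calculation and guards zero variance", {
  vals <- rbind(p1 = c(1, 3), p2 = c(5, 5), p3 = c(0, 2))
  colnames(vals) <- c("s1", "s2")
  m <- pm_of(vals, c("A", "A"))
  lv <- probe_log_variance(m)
  expect_equal(unname(lv["p1"]), log(2))            # var([1,3]) = 2
  expect_equal(unname(lv["p3"]), log(2))
  # constant probe: sentinel = min finite - 1
  expect_equal(unname(lv["p2"]), log(2) - 1)
})

test_that("log-variance separation of two noise scales is about 2 ln(10)", {
  set.seed(21)
  n <- 5000
  vals <- rbind(matrix(rnorm(n * 24, 5, 0.1), n),
                matrix(rnorm(n * 24, 5, 1.0), n))
  dimnames(vals) <- list(sprintf("p%05d", 1:(2 * n)), sprintf("s%02d", 1:24))
  m <- pm_of(vals, rep(c("A", "B", "C", "D", "E"), length.out = 24))
  lv <- probe_log_variance(m)
  gap <- mean(lv[(n + 1):(2 * n)]) - mean(lv[1:n])
  expect_equal(gap, 2 * log(10), tolerance = 0.05)
})

test_that("valley sits at the analytic mixture-density minimum", {
  # oracle: numeric minimization of the true two-Gaussian density
  cases <- list(c(w = 0.5, mu1 = -6, mu2 = -2, sd = 0.5),
                c(w = 0.66, mu1 = -6, mu2 = -2, sd = 0.5),
                c(w = 0.34, mu1 = -7, mu2 = -1.5, sd = 0.6))
  set.seed(33)
  for (s in cases) {
    n <- 20000
    n1 <- round(s["w"] * n)
    x <- c(rnorm(n1, s["mu1"], s["sd"]), rnorm(n - n1, s["mu2"], s["sd"]))
    mix <- function(t) s["w"] * dnorm(t, s["mu1"], s["sd"]) +
      (1 - s["w"]) * dnorm(t, s["mu2"], s["sd"])
    truth <- optimize(mix, c(s["mu1"], s["mu2"]))$minimum
    expect_equal(find_valley_threshold(x), truth, tolerance = 0.1,
                 ignore_attr = TRUE)
    # equal-weight symmetric case: valley at the midpoint -4
    if (s["w"] == 0.5) expect_equal(truth, -4, tolerance = 1e-3,
                                    ignore_attr = TRUE)
  }
})

test_that("unimodal input raises an explicit bimodality error", {
  set.seed(4)
  expect_error(find_valley_threshold(rnorm(5000, -3, 0.5)), "not bimodal")
})

test_that("variance classification applies the documented boundary rule", {
  lv <- setNames(c(-5, -3.74, -2, -4), paste0("p", 1:4))
  split <- classify_probe_variance(lv, -3.74)
  expect_setequal(split$low_probes, c("p1", "p4"))
  expect_setequal(split$high_probes, c("p2", "p3"))  # exactly at valley -> high
  # degenerate: all below valley
  s2 <- classify_probe_variance(lv, 10)
  expect_length(s2$high_probes, 0)
})

test_that("class proportions recover mixture weights within 2%", {
  set.seed(55)
  n <- 20000
  x <- c(rnorm(round(0.66 * n), -6, 0.5), rnorm(round(0.34 * n), -2, 0.5))
  names(x) <- sprintf("p%05d", seq_along(x))
  v <- find_valley_threshold(x)
  split <- classify_probe_variance(x, v)
  expect_equal(length(split$low_probes) / n, 0.66, tolerance = 0.02)
})

test_that("posterior matches the closed-form Gaussian posterior", {
  set.seed(77)
  n <- 10000
  vals_low <- rnorm(n, 2, 1)
  vals_high <- rnorm(n, 8, 1)
  x <- c(vals_low, vals_high, 5, 6)          # probe intensities incl. test points
  probes <- sprintf("p%05d", seq_along(x))
  vals <- matrix(rep(x, 2), ncol = 2, dimnames = list(probes, c("s1", "s2")))
  m <- pm_of(vals, c("A", "A"))
  lv <- setNames(c(rep(-5, n), rep(0, n), -5, 0), probes)
  split <- classify_probe_variance(lv, -2)
  closed <- function(t) dnorm(t, 8, 1) / (dnorm(t, 8, 1) + dnorm(t, 2, 1))

  post_g <- posterior_expressed(m, split, density_model = "gaussian")
  expect_lt(abs(post_g[n * 2 + 1, 1] - closed(5)), 0.02)
  expect_lt(abs(post_g[n * 2 + 2, 1] - closed(6)), 0.02)

  post_k <- posterior_expressed(m, split, density_model = "kde")
  expect_true(all(post_k >= 0 & post_k <= 1))
  expect_lt(abs(post_k[n * 2 + 2, 1] - closed(6)), 0.02)
  # in the inter-class gap the KDE posterior is noisy; sanity band only
  expect_lt(abs(post_k[n * 2 + 1, 1] - closed(5)), 0.25)
})

test_that("posterior is 0.5 under symmetric classes and monotone for Gaussian fits", {
  set.seed(78)
  # symmetric: low and high classes drawn from the same distribution
  x <- rnorm(2000, 5, 1)
  probes <- sprintf("p%04d", seq_along(x))
  vals <- matrix(rep(x, 2), ncol = 2, dimnames = list(probes, c("s1", "s2")))
  m <- pm_of(vals, c("A", "A"))
  lv <- setNames(rep(c(-5, 0), 1000), probes)
  split <- classify_probe_variance(lv, -2)
  post <- posterior_expressed(m, split, density_model = "gaussian")
  expect_equal(mean(post[, 1]), 0.5, tolerance = 0.05)

  # monotone in intensity when mean_high > mean_low (Gaussian model)
  set.seed(79)
  x2 <- c(rnorm(1000, 2, 1), rnorm(1000, 8, 1))
  probes2 <- sprintf("q%04d", seq_along(x2))
  vals2 <- matrix(rep(x2, 2), ncol = 2, dimnames = list(probes2, c("s1", "s2")))
  m2 <- pm_of(vals2, c("A", "A"))
  split2 <- classify_probe_variance(
    setNames(c(rep(-5, 1000), rep(0, 1000)), probes2), -2)
  post2 <- posterior_expressed(m2, split2, density_model = "gaussian")
  ord <- order(x2)
  expect_true(all(diff(post2[ord, 1]) >= -1e-12))
})

test_that("transcript and gene calls follow the min-arrays and any-transcript rules", {
  post <- rbind(p1 = c(0.99, 0.99, 0.99, 0.2, 0.2, 0.2),   # 3 arrays
                p2 = c(0.99, 0.99, 0.99, 0.99, 0.2, 0.2),  # 4 arrays
                p3 = rep(0.99, 6),
                p4 = rep(0.1, 6))
  colnames(post) <- paste0("s", 1:6)
  ann <- data.frame(probe_id = paste0("p", 1:4),
                    transcript_id = paste0("t", 1:4),
                    gene_id = c("g1", "g1", "g2", "g2"))
  tx <- call_transcripts(post, ann, posterior_threshold = 0.95, min_arrays = 4)
  expect_setequal(tx$expressed_transcripts, c("t2", "t3"))

  vals <- matrix(rep(c(5, 7, 9, 3), 6), nrow = 4,
                 dimnames = list(paste0("p", 1:4), paste0("s", 1:6)))
  m <- pm_of(vals, rep(c("A", "B", "C"), each = 2))
  genes <- collapse_genes(tx$expressed_transcripts, ann, m)
  expect_setequal(genes$expressed_genes, c("g1", "g2"))   # any-transcript rule
  expect_identical(unname(genes$representative_probe["g1"]), "p2")  # argmax mean
  expect_identical(unname(genes$representative_probe["g2"]), "p3")
  expect_length(intersect(genes$expressed_genes, genes$nonexpressed_genes), 0)
})

test_that("raising the posterior threshold never grows the expressed set", {
  d <- generate_dataset(sim_config(n_genes = 400, seed = 13))
  m <- quantile_normalize(d$matrix)
  lv <- probe_log_variance(m)
  split <- classify_probe_variance(lv, find_valley_threshold(lv))
  post <- posterior_expressed(m, split)
  prev <- NULL
  for (thr in c(0.5, 0.8, 0.95, 0.99)) {
    tx <- call_transcripts(post, d$annotation, posterior_threshold = thr)
    cur <- tx$expressed_transcripts
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("full pipeline equals a straight-line re-implementation on a toy matrix", {
  toy <- toy_bimodal_dataset()
  res <- call_expressed_genes(toy$m, toy$annotation, min_arrays = 2)

  # ---- straight-line oracle, written independently ----
  v <- toy$m$values
  lv <- log(apply(v, 1, var))
  d <- density(lv, bw = "nrd0", n = 512)
  pk <- which(diff(sign(diff(d$y))) == -2) + 1
  pk <- pk[d$y[pk] >= 0.05 * max(d$y)]
  pk2 <- pk[order(d$y[pk], decreasing = TRUE)][1:2]
  ii <- seq(min(pk2), max(pk2))
  valley <- d$x[ii[which.min(d$y[ii])]]
  low <- lv < valley
  pi_h <- mean(!low)
  post <- v * 0
  for (j in 1:ncol(v)) {
    dl <- density(v[low, j], n = 1024, cut = 4)
    dh <- density(v[!low, j], n = 1024, cut = 4)
    fl <- approx(dl$x, dl$y, v[, j], rule = 1)$y; fl[is.na(fl)] <- 0
    fh <- approx(dh$x, dh$y, v[, j], rule = 1)$y; fh[is.na(fh)] <- 0
    post[, j] <- pi_h * fh / (pi_h * fh + (1 - pi_h) * fl)
  }
  expressed_probes <- rownames(v)[rowSums(post > 0.95, na.rm = TRUE) >= 2]
  tx <- toy$annotation$transcript_id[match(expressed_probes, toy$annotation$probe_id)]
  genes <- sort(unique(toy$annotation$gene_id[toy$annotation$transcript_id %in% tx]))
  # ----------------------------------------------------

  expect_equal(res$valley, valley)
  expect_setequal(res$expressed_transcripts, tx)
  expect_identical(res$expressed_genes, genes)
  expect_setequal(c(res$expressed_genes, res$nonexpressed_genes),
                  unique(toy$annotation$gene_id))
})
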