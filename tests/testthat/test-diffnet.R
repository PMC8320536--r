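test_that("diff_network is the origin-tagged symmetric difference", {
  nt <- gene_network(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")))
  nn <- gene_network(data.frame(gene_a = c("B", "C"), gene_b = c("C", "D")))
  d <- diff_network(nt, nn)
  expect_equal(n_edges(d), 2L)
  expect_true(has_edge(d, "A", "B"))
  expect_true(has_edge(d, "C", "D"))
  expect_false(has_edge(d, "B", "C"))
  origins <- stats::setNames(d$edges$origin,
                             paste(d$edges$gene_a, d$edges$gene_b))
  expect_equal(unname(origins["A B"]), "tumor_only")
  expect_equal(unname(origins["C D"]), "normal_only")
  expect_equal(n_edges(diff_network(nt, nt)), 0L)
})

test_that("symmetric-difference size identity holds on random networks", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:12)
  pairs <- t(utils::combn(genes, 2))
  for (i in 1:20) {
    e1 <- pairs[sample(nrow(pairs), 25), ]
    e2 <- pairs[sample(nrow(pairs), 25), ]
    n1 <- gene_network(data.frame(gene_a = e1[, 1], gene_b = e1[, 2]))
    n2 <- gene_network(data.frame(gene_a = e2[, 1], gene_b = e2[, 2]))
    d <- diff_network(n1, n2)
    common <- length(intersect(edge_keys(n1), edge_keys(n2)))
    expect_equal(n_edges(d), n_edges(n1) + n_edges(n2) - 2L * common)
  }
})

# two genes x two sites each with controlled site-pair correlations
meth_fixture <- function(rho_t, rho_n, n_t = 60, n_n = 60, seed = 32) {
  set.seed(seed)
  samples <- c(sprintf("T%02d", seq_len(n_t)), sprintf("N%02d", seq_len(n_n)))
  labels <- stats::setNames(
    factor(rep(c("tumor", "normal"), c(n_t, n_n)), c("normal", "tumor")),
    samples)
  base_t <- stats::rnorm(n_t); base_n <- stats::rnorm(n_n)
  corr_with <- function(base, rho) rho * base +
    sqrt(1 - rho^2) * stats::rnorm(length(base))
  # a1 is the driver; b1 tracks it with group-specific correlation
  a1 <- c(base_t, base_n)
  b1 <- c(corr_with(base_t, rho_t), corr_with(base_n, rho_n))
  a2 <- stats::rnorm(n_t + n_n)
  b2 <- stats::rnorm(n_t + n_n)
  vals <- stats::plogis(rbind(cga1 = a1, cga2 = a2, cgb1 = b1, cgb2 = b2))
  colnames(vals) <- samples
  list(meth = list(values = vals,
                   site_gene = c(cga1 = "GA", cga2 = "GA",
                                 cgb1 = "GB", cgb2 = "GB")),
       labels = labels)
}

test_that("edge methylation score is the max |r_t - r_n| over site pairs", {
  fx <- meth_fixture(rho_t = 0.95, rho_n = -0.5)
  s <- edge_methylation_score(c("GA", "GB"), fx$meth, fx$labels)
  expect_equal(s$n_site_pairs, 4L)
  expect_equal(s$best_site_pair, c("cga1", "cgb1"))
  # oracle: recompute all four differences directly
  v <- fx$meth$values
  st <- names(fx$labels)[fx$labels == "tumor"]
  sn <- names(fx$labels)[fx$labels == "normal"]
  d <- sapply(c("cgb1", "cgb2"), function(b) sapply(c("cga1", "cga2"),
    function(a) abs(stats::cor(v[a, st], v[b, st]) -
                      stats::cor(v[a, sn], v[b, sn]))))
  expect_equal(s$score, max(d), tolerance = 1e-12)
  # symmetric in gene order
  s2 <- edge_methylation_score(c("GB", "GA"), fx$meth, fx$labels)
  expect_equal(s2$score, s$score)
  expect_equal(s2$best_site_pair, rev(s$best_site_pair))
})

test_that("identical group distributions give near-zero scores", {
  fx <- meth_fixture(rho_t = 0.4, rho_n = 0.4, n_t = 2000, n_n = 2000)
  s <- edge_methylation_score(c("GA", "GB"), fx$meth, fx$labels)
  expect_lt(s$score, 0.15)
})

test_that("build_diff_mn applies a strict threshold and coverage rule", {
  fx <- meth_fixture(rho_t = 0.95, rho_n = -0.5)
  dp <- gene_network(data.frame(
    gene_a = c("GA", "GA"), gene_b = c("GB", "GC"),
    origin = "tumor_only"))
  # GC has no mapped site: its edge is skipped with a message
  expect_message(mn <- build_diff_mn(dp, fx$meth, fx$labels, 0.7),
                 "without methylation coverage")
  expect_true(has_edge(mn, "GA", "GB"))
  expect_true(all(edge_keys(mn) %in% edge_keys(dp)))
  s <- edge_methylation_score(c("GA", "GB"), fx$meth, fx$labels)$score
  # strictness: a threshold at exactly the score excludes the edge
  expect_message(at <- build_diff_mn(dp, fx$meth, fx$labels, s))
  expect_equal(n_edges(at), 0L)
  # monotonicity: raising the threshold never adds edges
  expect_message(lo <- build_diff_mn(dp, fx$meth, fx$labels, 0.2))
  expect_message(hi <- build_diff_mn(dp, fx$meth, fx$labels, 0.9))
  expect_true(all(edge_keys(hi) %in% edge_keys(lo)))
})
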