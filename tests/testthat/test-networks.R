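# helper: expression matrix from a samples x genes latent matrix
expr_from_latent <- function(Z, prefix = "S") {
  if (is.null(colnames(Z))) colnames(Z) <- sprintf("g%02d", seq_len(ncol(Z)))
  rownames(Z) <- sprintf("%s%03d", prefix, seq_len(nrow(Z)))
  t(Z - min(Z))
}

test_that("build_pccn keeps a planted correlated pair among null edges", {
  set.seed(21)
  n <- 50
  n_null_genes <- 20
  Z <- matrix(stats::rnorm(n * (n_null_genes + 2)), n)
  # plant a bivariate-normal pair with rho = 0.9 in the first two columns
  Z[, 2] <- 0.9 * Z[, 1] + sqrt(1 - 0.81) * stats::rnorm(n)
  expr <- expr_from_latent(Z)
  genes <- rownames(expr)
  # background: the planted edge plus 100 null edges
  null_pairs <- t(utils::combn(genes[-(1:2)], 2))[1:100, ]
  bg <- gene_network(data.frame(
    gene_a = c(genes[1], null_pairs[, 1]),
    gene_b = c(genes[2], null_pairs[, 2])))
  labels <- stats::setNames(factor(rep("tumor", n), c("normal", "tumor")),
                            colnames(expr))
  pccn <- build_pccn(expr, bg, labels, "tumor", pearson_alpha = 0.01)
  expect_true(has_edge(pccn, genes[1], genes[2]))
  expect_true(all(edge_keys(pccn) %in% edge_keys(bg)))
  expect_true(all(pccn$edges$p_adj < 0.01))
  expect_true(all(pccn$edges$p_adj >= pccn$edges$p))
})

test_that("all-null networks keep at most the BH-nominal fraction of edges", {
  set.seed(22)
  kept <- numeric(200)
  genes <- sprintf("g%02d", 1:15)
  pairs <- t(utils::combn(genes, 2))[1:50, ]
  bg <- gene_network(data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2]))
  for (i in seq_along(kept)) {
    expr <- expr_from_latent(matrix(stats::rnorm(30 * 15), 30,
                                    dimnames = list(NULL, genes)))
    labels <- stats::setNames(factor(rep("tumor", 30), c("normal", "tumor")),
                              colnames(expr))
    kept[i] <- n_edges(build_pccn(expr, bg, labels, "tumor", 0.01)) / 50
  }
  expect_lte(mean(kept), 0.01)
  # degenerate input: empty background -> empty PCCN
  expr <- expr_from_latent(matrix(stats::rnorm(30 * 15), 30,
                                  dimnames = list(NULL, genes)))
  labels <- stats::setNames(factor(rep("tumor", 30), c("normal", "tumor")),
                            colnames(expr))
  expect_equal(n_edges(build_pccn(expr, gene_network(), labels, "tumor")), 0L)
  expect_error(build_pccn(expr[, 1:2], bg, labels[1:2], "tumor"),
               "at least 3")
})

test_that("edge_partial_test selects the minimum-|partial| common neighbor", {
  set.seed(23)
  n <- 300
  z <- stats::rnorm(n)                                  # strong common cause
  x <- 0.8 * z + stats::rnorm(n, sd = 0.6)
  y <- 0.8 * z + stats::rnorm(n, sd = 0.6)
  w <- 0.3 * x + 0.3 * y + stats::rnorm(n)              # weak common neighbor
  expr <- t(cbind(x = x, y = y, z = z, w = w) - min(c(x, y, z, w)))
  colnames(expr) <- sprintf("S%03d", 1:n)
  labels <- stats::setNames(factor(rep("tumor", n), c("normal", "tumor")),
                            colnames(expr))
  pccn <- gene_network(data.frame(
    gene_a = c("x", "x", "y", "x", "y"),
    gene_b = c("y", "z", "z", "w", "w")))
  res <- edge_partial_test(c("x", "y"), pccn, expr, labels, "tumor")
  expect_equal(res$k_selected, "z")     # z explains x-y away, w does not
  expect_equal(res$order, 1L)
  R <- stats::cor(t(expr))
  expected <- min(abs(first_order_partial(R["x", "y"], R["x", c("z", "w")],
                                          R["y", c("z", "w")])))
  expect_equal(abs(res$r_partial), expected, tolerance = 1e-12)
  # no common neighbor: falls back to the zero-order correlation
  sparse <- gene_network(data.frame(gene_a = c("x", "z"),
                                    gene_b = c("w", "w")))
  res0 <- edge_partial_test(c("x", "w"), sparse, expr, labels, "tumor")
  expect_equal(res0$order, 0L)
  expect_true(is.na(res0$k_selected))
  expect_equal(res0$r_partial, unname(R["x", "w"]), tolerance = 1e-12)
  expect_error(edge_partial_test(c("z", "w"), pccn, expr, labels, "tumor"),
               "not a PCCN edge")
})

test_that("chain-induced indirect edges are removed while direct edges survive", {
  set.seed(24)
  n <- 200
  k <- stats::rnorm(n)
  i <- 0.7 * k + stats::rnorm(n, sd = sqrt(0.51))
  j <- 0.7 * k + stats::rnorm(n, sd = sqrt(0.51))
  expr <- t(cbind(i = i, k = k, j = j) + 10)
  colnames(expr) <- sprintf("S%03d", 1:n)
  labels <- stats::setNames(factor(rep("tumor", n), c("normal", "tumor")),
                            colnames(expr))
  bg <- gene_network(data.frame(gene_a = c("i", "k", "i"),
                                gene_b = c("k", "j", "j")))
  pccn <- build_pccn(expr, bg, labels, "tumor", 0.01)
  expect_true(has_edge(pccn, "i", "j"))    # marginally correlated
  pcorn <- build_pcorn(pccn, expr, labels, "tumor", 0.05)
  expect_false(has_edge(pcorn, "i", "j"))  # explained by k
  expect_true(has_edge(pcorn, "i", "k"))
  expect_true(has_edge(pcorn, "k", "j"))
  expect_true(all(edge_keys(pcorn) %in% edge_keys(pccn)))
  # empty PCCN propagates
  expect_equal(n_edges(build_pcorn(gene_network(), expr, labels, "tumor")), 0L)
})

test_that("PCORN retains most planted direct edges at n = 200", {
  set.seed(25)
  retained <- total <- 0
  for (rep in 1:5) {
    sim <- simulate_omics(synthetic_config(n_tumor = 200, n_normal = 200,
                                           n_genes = 150, n_disease_genes = 5,
                                           n_indirect_chains = 10,
                                           seed = 300 + rep))
    fit <- recover_truth(sim)$fit
    tr <- sim$truth$direct_edges_tumor
    pk <- pair_key(tr$gene_a, tr$gene_b)
    retained <- retained + sum(pk %in% edge_keys(fit$networks$pcorn$tumor))
    total <- total + length(pk)
  }
  expect_gte(retained / total, 0.9)
})
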