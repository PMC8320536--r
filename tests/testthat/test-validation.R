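test_that("hypergeometric tail matches exhaustive enumeration for small N", {
  expect_equal(hypergeom_tail(10, 4, 3, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_tail(6, 3, 3, 3), 0.05, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 4, 3, 0), 1)
  set.seed(51)
  for (i in 1:30) {
    N <- sample(4:12, 1)
    M <- sample(1:N, 1)
    n <- sample(1:N, 1)
    x <- sample(0:min(M, n), 1)
    expect_equal(hypergeom_tail(N, M, n, x),
                 hypergeom_enum_oracle(N, M, n, x), tolerance = 1e-12)
  }
  expect_error(hypergeom_tail(10, 4, 3, 4), "infeasible")
})

test_that("hypergeometric tail matches the reference CDF at genome scale", {
  cases <- list(c(19600, 723, 15, 9), c(19600, 531, 15, 4),
                c(19600, 168, 15, 4), c(100000, 500, 20, 3),
                c(16264, 723, 15, 9))
  for (cs in cases) {
    expect_lt(abs(hypergeom_tail(cs[1], cs[2], cs[3], cs[4]) -
                    stats::phyper(cs[4] - 1, cs[2], cs[1] - cs[2], cs[3],
                                  lower.tail = FALSE)),
              1e-12)
  }
})

test_that("classification separates shifted groups and is calibrated under nulls", {
  fx <- shifted_expression(seed = 52)
  rep <- classify_cv(fx$expr, fx$shifted, fx$labels, seed = 1)
  expect_gte(rep$auc, 0.99)
  expect_equal(rep$fold_count, 5L)
  expect_true(rep$oversampled)
  # ROC points are monotone nondecreasing in both coordinates
  expect_true(all(diff(rep$roc_points$fpr) >= 0))
  expect_true(all(diff(rep$roc_points$tpr) >= 0))
  # AUC equals the rank/Mann-Whitney oracle on the pooled scores
  expect_equal(rep$auc, auc_rank_oracle(rep$scores, fx$labels),
               tolerance = 1e-12)
  # permuted labels: mean AUC near 0.5
  set.seed(53)
  aucs <- replicate(20, {
    perm <- stats::setNames(sample(fx$labels), names(fx$labels))
    classify_cv(fx$expr, fx$shifted, perm, seed = 2)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("AUC is invariant to monotone transforms of the features", {
  fx <- shifted_expression(n_tumor = 20, n_normal = 20, shift = 2, seed = 54)
  a1 <- classify_cv(fx$expr, fx$shifted, fx$labels, seed = 3)$auc
  # scores, not features, determine the ROC: transform the pooled scores
  rep <- classify_cv(fx$expr, fx$shifted, fx$labels, seed = 3)
  tr <- pROC::roc(response = fx$labels[names(rep$scores)],
                  predictor = exp(rep$scores / 2),
                  levels = c("normal", "tumor"), direction = "<",
                  quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(tr)), a1, tolerance = 1e-12)
})

test_that("classification errors are actionable", {
  fx <- shifted_expression(n_tumor = 3, n_normal = 30, seed = 55)
  expect_error(classify_cv(fx$expr, fx$shifted, fx$labels, folds = 5),
               "fewer folds")
  expect_error(classify_cv(fx$expr, c("nope"), fx$labels), "not in expression")
})

test_that("single-linkage cityblock clustering separates two blobs", {
  set.seed(56)
  genes <- sprintf("g%d", 1:10)
  tumor <- matrix(stats::rnorm(10 * 15, mean = 0), 10)
  normal <- matrix(stats::rnorm(10 * 8, mean = 8), 10)
  expr <- cbind(tumor, normal) - min(cbind(tumor, normal))
  dimnames(expr) <- list(genes, c(sprintf("t%02d", 1:15), sprintf("n%02d", 1:8)))
  labels <- stats::setNames(
    factor(rep(c("tumor", "normal"), c(15, 8)), c("normal", "tumor")),
    colnames(expr))
  rep <- cluster_samples(expr, genes, labels)
  expect_equal(rep$normal_cluster_recall, 1)
  expect_equal(rep$linkage, "single")
  expect_equal(rep$metric, "cityblock")
  # invariance to sample order (up to relabeling): recall is unchanged
  perm <- sample(ncol(expr))
  rep2 <- cluster_samples(expr[, perm], genes, labels[perm])
  expect_equal(rep2$normal_cluster_recall, 1)
  # degenerate: identical sample vectors warn
  flat <- matrix(1, 10, 4, dimnames = list(genes, paste0("s", 1:4)))
  lf <- stats::setNames(factor(c("tumor", "tumor", "normal", "normal"),
                               c("normal", "tumor")), colnames(flat))
  expect_warning(cluster_samples(flat, genes, lf), "degenerate")
})

test_that("per-gene Welch tests match t.test and detect planted shifts", {
  fx <- shifted_expression(n_tumor = 50, n_normal = 50, shift = 3, seed = 57)
  res <- per_gene_differential_test(fx$expr, rownames(fx$expr), fx$labels)
  shifted <- res[res$gene %in% fx$shifted, ]
  expect_true(all(shifted$p < 1e-6))
  expect_true(all(shifted$direction == "up"))
  null_p <- res$p[!res$gene %in% fx$shifted]
  expect_gt(mean(null_p), 0.2)   # roughly uniform under the null
  # equal-variance toy against a direct hand computation
  g <- fx$shifted[1]
  st <- names(fx$labels)[fx$labels == "tumor"]
  sn <- names(fx$labels)[fx$labels == "normal"]
  ref <- stats::t.test(fx$expr[g, st], fx$expr[g, sn])
  expect_equal(res$t[res$gene == g], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p[res$gene == g], ref$p.value, tolerance = 1e-12)
})
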