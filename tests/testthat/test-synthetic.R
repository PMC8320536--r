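test_that("generation is deterministic and respects value ranges", {
  cfg <- synthetic_config(n_genes = 80, n_tumor = 30, n_normal = 20,
                          n_disease_genes = 3, disease_edges_per_gene = 3,
                          n_indirect_chains = 5, seed = 7)
  a <- simulate_omics(cfg)
  b <- simulate_omics(cfg)
  expect_identical(a$data$expr, b$data$expr)
  expect_identical(a$data$meth$values, b$data$meth$values)
  expect_identical(a$data$mut$records, b$data$mut$records)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$data$expr >= 0))
  mv <- a$data$meth$values
  expect_true(all(mv[!is.na(mv)] >= 0 & mv[!is.na(mv)] <= 1))
  expect_equal(sum(a$data$labels == "tumor"), 30L)
  expect_equal(sum(a$data$labels == "normal"), 20L)
  # indirect pairs never coincide with planted direct edges
  dk <- c(pair_key(a$truth$direct_edges_tumor$gene_a,
                   a$truth$direct_edges_tumor$gene_b),
          pair_key(a$truth$direct_edges_normal$gene_a,
                   a$truth$direct_edges_normal$gene_b))
  ik <- pair_key(a$truth$indirect_pairs$gene_a, a$truth$indirect_pairs$gene_b)
  expect_length(intersect(ik, dk), 0L)
  # overly strong planted strengths are rejected, naming the cause
  expect_error(simulate_omics(synthetic_config(direct_edge_strength = 0.9,
                                               n_genes = 200)),
               "positive definite")
})

test_that("planted full partial correlations converge to the configured strength", {
  # on the untransformed (Gaussian) scale the inverse sample correlation
  # matrix recovers the planted partial correlations
  cfg <- synthetic_config(n_genes = 120, n_tumor = 2000, n_normal = 4,
                          n_disease_genes = 4, disease_edges_per_gene = 4,
                          n_indirect_chains = 8, fpkm_transform = FALSE,
                          disease_expression_shift = 0, seed = 8)
  sim <- simulate_omics(cfg)
  tum <- names(sim$data$labels)[sim$data$labels == "tumor"]
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  R <- stats::cor(t(sim$data$expr[genes, tum]))
  P <- solve(R)
  pc <- -stats::cov2cor(P)
  tr <- sim$truth$direct_edges_tumor
  star_k <- pair_key(sim$truth$differential_meth_edges$gene_a,
                     sim$truth$differential_meth_edges$gene_b)
  expected <- ifelse(pair_key(tr$gene_a, tr$gene_b) %in% star_k,
                     min(cfg$direct_edge_strength,
                         0.9 / sqrt(cfg$disease_edges_per_gene)),
                     cfg$direct_edge_strength)
  got <- pc[cbind(match(tr$gene_a, genes), match(tr$gene_b, genes))]
  expect_lt(mean(abs(got - expected)), 0.05)
  expect_lt(max(abs(got - expected)), 0.1)
  # indirect pairs have (near) zero partial correlation
  ip <- sim$truth$indirect_pairs
  got0 <- pc[cbind(match(ip$gene_a, genes), match(ip$gene_b, genes))]
  expect_lt(mean(abs(got0)), 0.05)
})

test_that("chain endpoints correlate marginally but only indirectly", {
  sim <- simulate_omics(synthetic_config(n_tumor = 200, n_normal = 200,
                                         seed = 9))
  tum <- names(sim$data$labels)[sim$data$labels == "tumor"]
  ip <- sim$truth$indirect_pairs
  p <- mapply(function(a, b) {
    pearson_r_p(sim$data$expr[a, tum], sim$data$expr[b, tum])$p
  }, ip$gene_a, ip$gene_b)
  # at BH 0.01 within this small family, at least 90% detectable
  expect_gte(mean(bh_adjust(p) < 0.01), 0.9)
})

test_that("null configuration yields exchangeable groups and chance recovery", {
  sim <- simulate_omics(null_synthetic_config(seed = 10))
  expect_equal(nrow(sim$truth$direct_edges_tumor), 0L)
  expect_equal(nrow(sim$truth$indirect_pairs), 0L)
  rec <- suppressWarnings(recover_truth(sim))
  expect_lte(unname(rec$metrics["disease_gene_recall"]), 0.3)
  expect_lte(n_edges(rec$fit$networks$diff_mn), 5L)
})

test_that("written files round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_omics(synthetic_config(n_genes = 80, n_tumor = 20,
                                         n_normal = 10, n_disease_genes = 3,
                                         disease_edges_per_gene = 3,
                                         n_indirect_chains = 5, seed = 11))
  paths <- write_omics(sim, dir)
  ed <- read_expression(paths["expression"], paths["labels"])
  expect_equal(ed$expr, sim$data$expr)
  expect_equal(ed$labels, sim$data$labels)
  meth <- read_methylation(paths["methylation"],
                           paths["methylation_annotation"])
  expect_equal(meth$values, sim$data$meth$values)
  expect_equal(meth$site_gene, sim$data$meth$site_gene)
  mut <- read_mutations(paths["mutations"])
  expect_equal(mut$records, sim$data$mut$records)
  ppi <- read_ppi(paths["ppi"])
  expect_equal(ppi$edges, sim$ppi$edges)
})

test_that("recovery metrics are computed against the planted truth", {
  sim <- simulate_omics(synthetic_config(seed = 12))
  rec <- recover_truth(sim)
  m <- rec$metrics
  expect_true(m["disease_gene_recall"] >= 0 && m["disease_gene_recall"] <= 1)
  expect_lte(m["n_selected"], 10)
  expect_true(m["indirect_removed_fraction"] >= 0 &&
                m["indirect_removed_fraction"] <= 1)
  sel <- attr(rec$fit$candidates, "selected")
  expect_equal(unname(m["disease_gene_recall"]),
               length(intersect(sel, sim$truth$disease_genes)) /
                 length(sim$truth$disease_genes))
})
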