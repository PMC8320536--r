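#' Configuration for the synthetic multi-omics generator
#'
#' Defines the simulated study conditions: a Gaussian graphical model per
#' group whose precision matrix encodes planted direct gene-gene edges,
#' disease genes that gain tumor-only edges, i-k-j chains whose endpoints
#' correlate only indirectly, group-differential co-methylation on the
#' disease edges, and elevated somatic mutation rates in disease genes.
#'
#' Planted structure is laid out in vertex-disjoint components (disease
#' stars, chains, a backbone matching) so the precision matrix stays
#' positive definite at interpretable strengths: a star of degree d with
#' uniform partial correlation s requires `s < 1/sqrt(d)`, so star edges
#' are capped at `0.9 / sqrt(disease_edges_per_gene)`.
#'
#' @param n_genes number of genes in the universe (default 200)
#' @param n_tumor,n_normal per-group sample counts (defaults 120, 40)
#' @param background_degree average degree of the null PPI scaffold
#' @param n_disease_genes planted disease genes (default 10)
#' @param disease_edges_per_gene tumor-only direct edges per disease gene
#' @param direct_edge_strength partial-correlation magnitude of planted
#'   direct edges (backbone and chain links; star edges capped as above)
#' @param n_indirect_chains planted i-k-j chains with a PPI shortcut i-j but
#'   no direct i-j dependence
#' @param sites_per_gene inclusive range of methylation sites per gene
#' @param diff_meth_effect target `|r_tumor - r_normal|` on planted
#'   differential site pairs (in \[0, 2\])
#' @param disease_mutation_rate,background_mutation_rate per-tumor-sample
#'   Bernoulli mutation rates
#' @param disease_expression_shift additive tumor-group shift of disease
#'   genes on the latent log scale (gives the module a supervised signal)
#' @param expression_sd latent log-scale standard deviation
#' @param fpkm_transform exponentiate the latent Gaussian to an FPKM-like
#'   scale (a monotone stressor for Pearson-based inference); FALSE keeps a
#'   shifted Gaussian scale
#' @param n_unexpressed decoy genes expressed in under half the samples
#'   (exercise the expression filter)
#' @param n_decoy_sites decoy methylation sites with multi-gene annotation
#'   or missing values (exercise the site filter)
#' @param seed RNG seed; the whole dataset is reproducible from it
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(n_genes = 200, n_tumor = 120, n_normal = 40,
                             background_degree = 4, n_disease_genes = 10,
                             disease_edges_per_gene = 5,
                             direct_edge_strength = 0.5,
                             n_indirect_chains = 20,
                             sites_per_gene = c(1, 3),
                             diff_meth_effect = 1.2,
                             disease_mutation_rate = 0.4,
                             background_mutation_rate = 0.02,
                             disease_expression_shift = 1,
                             expression_sd = 0.4,
                             fpkm_transform = TRUE,
                             n_unexpressed = 10, n_decoy_sites = 6,
                             seed = 1) {
  cfg <- list(n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
              background_degree = background_degree,
              n_disease_genes = n_disease_genes,
              disease_edges_per_gene = disease_edges_per_gene,
              direct_edge_strength = direct_edge_strength,
              n_indirect_chains = n_indirect_chains,
              sites_per_gene = sites_per_gene,
              diff_meth_effect = diff_meth_effect,
              disease_mutation_rate = disease_mutation_rate,
              background_mutation_rate = background_mutation_rate,
              disease_expression_shift = disease_expression_shift,
              expression_sd = expression_sd,
              fpkm_transform = fpkm_transform,
              n_unexpressed = n_unexpressed, n_decoy_sites = n_decoy_sites,
              seed = seed)
  stopifnot(cfg$direct_edge_strength >= 0, cfg$direct_edge_strength < 1,
            cfg$diff_meth_effect >= 0, cfg$diff_meth_effect <= 2,
            all(c(cfg$disease_mutation_rate, cfg$background_mutation_rate) >= 0),
            all(c(cfg$disease_mutation_rate, cfg$background_mutation_rate) <= 1),
            length(sites_per_gene) == 2, sites_per_gene[1] >= 1,
            n_tumor >= 4, n_normal >= 4)
  need <- n_disease_genes * (1 + disease_edges_per_gene) + 3 * n_indirect_chains
  if (n_genes < need + 2)
    stop(sprintf("n_genes = %d too small for the planted structure (need >= %d)",
                 n_genes, need + 2))
  structure(cfg, class = "synthetic_config")
}

# sample `n` rows from N(0, C) with unit variances, via Cholesky
rmvn_corr <- function(n, C) {
  matrix(stats::rnorm(n * ncol(C)), n, ncol(C)) %*% chol(C)
}

# correlation matrix of the Gaussian graphical model with unit-diagonal
# precision and entries -strength on the given edges; errors when the
# planted strengths break positive definiteness
ggm_correlation <- function(genes, edges, strengths, label) {
  n <- length(genes)
  P <- diag(n)
  dimnames(P) <- list(genes, genes)
  if (nrow(edges)) {
    ia <- match(edges$gene_a, genes)
    ib <- match(edges$gene_b, genes)
    P[cbind(ia, ib)] <- -strengths
    P[cbind(ib, ia)] <- -strengths
  }
  ev <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-3)
    stop(sprintf("precision matrix not positive definite (%s): %s",
                 label, "reduce direct_edge_strength or planted degrees"))
  stats::cov2cor(solve(P))
}

#' Generate a synthetic multi-omics dataset with known ground truth
#'
#' See [synthetic_config()] for the model. Expression is drawn per group
#' from a zero-mean Gaussian graphical model, shifted and (by default)
#' exponentiated to a non-negative FPKM-like scale. Methylation Beta values
#' are a logistic squash of correlated Gaussians whose site-site correlation
#' differs between groups by about `diff_meth_effect` on planted
#' differential site pairs. Mutations are Bernoulli per gene per tumor
#' sample. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()]
#' @return list of class `synthetic_omics` with elements `data` (an
#'   [omics_dataset()]), `ppi` (a [gene_network] with confidence scores),
#'   `truth` (disease genes, per-group direct edge sets, indirect pairs,
#'   differential methylation edges) and `config`
#' @export
simulate_omics <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  samples <- c(sprintf("T%03d", seq_len(cfg$n_tumor)),
               sprintf("N%03d", seq_len(cfg$n_normal)))
  labels <- stats::setNames(
    factor(rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal)),
           levels = c("normal", "tumor")), samples)
  tumor_cols <- which(labels == "tumor")
  normal_cols <- which(labels == "normal")

  # --- role assignment (vertex-disjoint planted components) ---------------
  perm <- sample(genes)
  nd <- cfg$n_disease_genes; dpg <- cfg$disease_edges_per_gene
  disease <- sort(perm[seq_len(nd)])
  used <- nd
  partners <- matrix(perm[used + seq_len(nd * dpg)], nrow = nd, byrow = TRUE)
  used <- used + nd * dpg
  chains <- matrix(perm[used + seq_len(3 * cfg$n_indirect_chains)],
                   ncol = 3, byrow = TRUE)   # columns: i, k, j
  used <- used + 3 * cfg$n_indirect_chains
  rest <- perm[(used + 1):length(perm)]
  n_pairs <- floor(length(rest) / 2)
  backbone <- if (n_pairs) matrix(rest[seq_len(2 * n_pairs)], ncol = 2,
                                  byrow = TRUE) else matrix(character(), 0, 2)

  s <- cfg$direct_edge_strength
  s_star <- min(s, 0.9 / sqrt(max(dpg, 1)))
  pair_df <- function(a, b) data.frame(gene_a = pmin(a, b),
                                       gene_b = pmax(a, b),
                                       stringsAsFactors = FALSE)
  star_edges <- pair_df(rep(disease, each = dpg), as.vector(t(partners)))
  link_edges <- rbind(pair_df(chains[, 1], chains[, 2]),
                      pair_df(chains[, 2], chains[, 3]))
  shortcut_edges <- pair_df(chains[, 1], chains[, 3])
  backbone_edges <- if (nrow(backbone)) pair_df(backbone[, 1], backbone[, 2])
                    else pair_df(character(), character())

  shared <- rbind(link_edges, backbone_edges)
  normal_edges <- shared
  tumor_edges <- rbind(shared, star_edges)
  C_t <- ggm_correlation(genes, tumor_edges,
                         c(rep(s, nrow(shared)), rep(s_star, nrow(star_edges))),
                         "tumor group")
  C_n <- ggm_correlation(genes, normal_edges, rep(s, nrow(normal_edges)),
                         "normal group")

  # --- expression ---------------------------------------------------------
  mu <- stats::setNames(stats::rnorm(length(genes), mean = 2), genes)
  Z <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))
  Z[tumor_cols, ] <- rmvn_corr(cfg$n_tumor, C_t)
  Z[normal_cols, ] <- rmvn_corr(cfg$n_normal, C_n)
  L <- sweep(cfg$expression_sd * Z, 2, mu, `+`)
  L[tumor_cols, disease] <- L[tumor_cols, disease] + cfg$disease_expression_shift
  expr <- t(if (cfg$fpkm_transform) exp(L) else pmax(L + 6, 0))

  if (cfg$n_unexpressed > 0) {
    dec <- sprintf("U%03d", seq_len(cfg$n_unexpressed))
    dm <- matrix(0, cfg$n_unexpressed, length(samples),
                 dimnames = list(dec, samples))
    n_on <- floor(0.3 * length(samples))
    for (i in seq_len(cfg$n_unexpressed)) {
      on <- sample(length(samples), n_on)
      dm[i, on] <- exp(stats::rnorm(n_on))
    }
    expr <- rbind(expr, dm)
  }

  # --- PPI scaffold -------------------------------------------------------
  planted <- rbind(tumor_edges, shortcut_edges)
  all_nodes <- rownames(expr)
  n_null <- round(cfg$n_genes * cfg$background_degree / 2)
  na_ <- sample(all_nodes, 3 * n_null, replace = TRUE)
  nb_ <- sample(all_nodes, 3 * n_null, replace = TRUE)
  ok <- na_ != nb_
  null_edges <- unique(pair_df(na_[ok], nb_[ok]))
  null_edges <- null_edges[!(paste(null_edges$gene_a, null_edges$gene_b) %in%
                               paste(planted$gene_a, planted$gene_b)), ]
  null_edges <- utils::head(null_edges, n_null)
  conf_planted <- sample(600:999, nrow(planted), replace = TRUE)
  n_low <- round(0.3 * nrow(null_edges))
  conf_null <- c(sample(100:500, n_low, replace = TRUE),
                 sample(501:999, nrow(null_edges) - n_low, replace = TRUE))
  ppi <- gene_network(data.frame(
    rbind(planted, null_edges),
    confidence = c(conf_planted, sample(conf_null)),
    stringsAsFactors = FALSE))

  # --- methylation --------------------------------------------------------
  k_sites <- sample(cfg$sites_per_gene[1]:cfg$sites_per_gene[2],
                    length(genes), replace = TRUE)
  site_gene <- rep(genes, k_sites)
  site_ids <- sprintf("cg%06d", seq_along(site_gene))
  names(site_gene) <- site_ids
  first_site <- stats::setNames(site_ids[!duplicated(site_gene)],
                                site_gene[!duplicated(site_gene)])
  f <- matrix(stats::rnorm(length(samples) * length(genes)),
              length(samples), length(genes), dimnames = list(samples, genes))
  Xs <- sqrt(0.5) * f[, site_gene] +
    sqrt(0.5) * matrix(stats::rnorm(length(samples) * length(site_ids)),
                       length(samples), length(site_ids))
  colnames(Xs) <- site_ids
  rho_t <- min(0.95, 0.2 + cfg$diff_meth_effect / 2)
  rho_n <- max(-0.95, rho_t - cfg$diff_meth_effect)
  mix <- function(u, rho, rows) {
    rho * Xs[rows, u] + sqrt(1 - rho^2) * stats::rnorm(length(rows))
  }
  # plant on the (center, partner) orientation: the partner's site is the
  # one rewritten, so a disease hub keeps one intact site across its edges
  star_centers <- rep(disease, each = dpg)
  star_partners <- as.vector(t(partners))
  for (e in seq_along(star_centers)) {
    u <- first_site[star_centers[e]]
    v <- first_site[star_partners[e]]
    Xs[tumor_cols, v] <- mix(u, rho_t, tumor_cols)
    Xs[normal_cols, v] <- mix(u, rho_n, normal_cols)
  }
  mu_s <- stats::rnorm(length(site_ids))
  beta <- t(stats::plogis(sweep(Xs, 2, mu_s, `+`)))

  if (cfg$n_decoy_sites > 0) {
    nd2 <- cfg$n_decoy_sites
    dsid <- sprintf("cgDECOY%02d", seq_len(nd2))
    dvals <- matrix(stats::runif(nd2 * length(samples)), nd2, length(samples),
                    dimnames = list(dsid, samples))
    multi <- seq_len(ceiling(nd2 / 2))
    for (i in setdiff(seq_len(nd2), multi))
      dvals[i, sample(length(samples), 1)] <- NA
    dg <- character(nd2)
    dg[multi] <- paste(sample(genes, length(multi)),
                       sample(genes, length(multi)), sep = ";")
    dg[-multi] <- sample(genes, nd2 - length(multi))
    beta <- rbind(beta, dvals)
    site_gene <- c(site_gene, stats::setNames(dg, dsid))
  }
  meth <- list(values = beta, site_gene = site_gene)

  # --- mutations ----------------------------------------------------------
  rates <- stats::setNames(rep(cfg$background_mutation_rate, length(genes)),
                           genes)
  rates[disease] <- cfg$disease_mutation_rate
  tumor_ids <- samples[tumor_cols]
  hit <- matrix(stats::rbinom(length(genes) * length(tumor_ids), 1,
                              rep(rates, times = length(tumor_ids))),
                length(genes), length(tumor_ids),
                dimnames = list(genes, tumor_ids))
  idx <- which(hit == 1, arr.ind = TRUE)
  rec <- data.frame(gene = genes[idx[, 1]], sample = tumor_ids[idx[, 2]],
                    stringsAsFactors = FALSE)
  rec <- rec[order(rec$gene, rec$sample), , drop = FALSE]
  rownames(rec) <- NULL
  mut <- list(records = rec, sample_universe = tumor_ids)

  # a planted edge of strength zero carries no dependence: the truth sets
  # are empty under the null configuration
  empty_unless <- function(df, cond) if (cond) gene_network(df)$edges
    else gene_network()$edges
  truth <- list(
    disease_genes = disease,
    direct_edges_tumor = empty_unless(tumor_edges, s > 0 || s_star > 0),
    direct_edges_normal = empty_unless(normal_edges, s > 0),
    indirect_pairs = empty_unless(shortcut_edges, s > 0),
    differential_meth_edges = empty_unless(star_edges,
                                           cfg$diff_meth_effect > 0))
  structure(list(data = omics_dataset(expr, labels, meth = meth, mut = mut),
                 ppi = ppi, truth = truth, config = cfg),
            class = "synthetic_omics")
}

#' @export
print.synthetic_omics <- function(x, ...) {
  cat(sprintf("synthetic_omics (seed %d): %d genes, %d tumor / %d normal samples\n",
              x$config$seed, x$config$n_genes, x$config$n_tumor,
              x$config$n_normal))
  cat(sprintf("  planted: %d disease genes, %d tumor-only edges, %d chains\n",
              length(x$truth$disease_genes),
              nrow(x$truth$differential_meth_edges),
              nrow(x$truth$indirect_pairs)))
  invisible(x)
}

#' Null synthetic configuration (no planted structure)
#'
#' Groups are statistically exchangeable: no direct edges, no differential
#' methylation, equal mutation rates, no expression shift. Downstream
#' differential networks are empty in expectation and any selected gene set
#' is a chance draw.
#'
#' @param ... overrides passed to [synthetic_config()]
#' @return a `synthetic_config`
#' @export
null_synthetic_config <- function(...) {
  synthetic_config(direct_edge_strength = 0, diff_meth_effect = 0,
                   disease_mutation_rate = 0.02,
                   background_mutation_rate = 0.02,
                   disease_expression_shift = 0, ...)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Produces `expression.tsv`, `labels.tsv`, `methylation.tsv`,
#' `methylation_annotation.tsv`, `mutations.tsv`, `ppi.txt` and
#' `truth.json` under `dir`.
#'
#' @param sim a [simulate_omics()] result
#' @param dir output directory (created if absent)
#' @return named character vector of the written paths, invisibly
#' @export
write_omics <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  wr <- function(df, f) utils::write.table(df, p(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  d <- sim$data
  wr(data.frame(gene = rownames(d$expr), d$expr, check.names = FALSE),
     "expression.tsv")
  wr(data.frame(sample_id = names(d$labels), group = as.character(d$labels)),
     "labels.tsv")
  mv <- d$meth$values
  mdf <- data.frame(site = rownames(mv), mv, check.names = FALSE)
  wr(mdf, "methylation.tsv")
  wr(data.frame(site = names(d$meth$site_gene),
                gene = unname(d$meth$site_gene)),
     "methylation_annotation.tsv")
  wr(data.frame(Hugo_Symbol = d$mut$records$gene,
                Tumor_Sample_Barcode = d$mut$records$sample),
     "mutations.tsv")
  ppi <- sim$ppi$edges
  names(ppi) <- c("protein1", "protein2", "combined_score")
  utils::write.table(ppi, p("ppi.txt"), sep = " ", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(expression = p("expression.tsv"), labels = p("labels.tsv"),
              methylation = p("methylation.tsv"),
              methylation_annotation = p("methylation_annotation.tsv"),
              mutations = p("mutations.tsv"), ppi = p("ppi.txt"),
              truth = p("truth.json")))
}

#' Run the full pipeline on a synthetic dataset and score recovery
#'
#' Fits [dpcnet()] to the generated data and compares the result to the
#' planted ground truth: recall of disease genes among the selected module,
#' the fraction of indirect chain-endpoint edges present in a group's PCCN
#' that the partial-correlation step removed, and the fraction of planted
#' direct edges retained in the group's PCORN.
#'
#' @param sim a [simulate_omics()] result
#' @param config a [dpcnet_config()]; the default scales the ranking degree
#'   thresholds to the synthetic network size (Diff-PCORN degree > 3,
#'   Diff-MN degree > 2, top 10)
#' @return list with `metrics` (named numerics) and `fit` (the [dpcnet] object)
#' @export
recover_truth <- function(sim, config = dpcnet_config(
                            ranking = list(diff_pcorn_min_degree = 3,
                                           diff_mn_min_degree = 2,
                                           top_k = 10))) {
  fit <- dpcnet(sim$data, sim$ppi, config = config)
  truth <- sim$truth
  sel <- attr(fit$candidates, "selected")
  recall <- if (length(truth$disease_genes))
    length(intersect(sel, truth$disease_genes)) / length(truth$disease_genes)
  else NA_real_

  frac <- function(pairs, group) {
    pk <- pair_key(pairs$gene_a, pairs$gene_b)
    in_pccn <- pk %in% edge_keys(fit$networks$pccn[[group]])
    in_pcorn <- pk %in% edge_keys(fit$networks$pcorn[[group]])
    c(pccn = sum(in_pccn), removed = sum(in_pccn & !in_pcorn),
      retained = sum(in_pcorn), total = length(pk))
  }
  ind <- frac(truth$indirect_pairs, "tumor") +
    frac(truth$indirect_pairs, "normal")
  dir_t <- frac(truth$direct_edges_tumor, "tumor")
  dir_n <- frac(truth$direct_edges_normal, "normal")
  metrics <- c(
    disease_gene_recall = recall,
    n_selected = length(sel),
    indirect_in_pccn = unname(ind["pccn"]),
    indirect_removed_fraction =
      unname(if (ind["pccn"] > 0) ind["removed"] / ind["pccn"] else NA_real_),
    direct_retained_fraction =
      unname((dir_t["retained"] + dir_n["retained"]) /
               (dir_t["total"] + dir_n["total"])),
    direct_retained_in_pccn_fraction =
      unname(if ((dir_t["pccn"] + dir_n["pccn"]) > 0)
        (dir_t["retained"] + dir_n["retained"]) /
          (dir_t["pccn"] + dir_n["pccn"]) else NA_real_)
  )
  list(metrics = metrics, fit = fit)
}
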