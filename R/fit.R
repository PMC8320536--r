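#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the liver-cancer
#' defaults. Partial lists are merged over the defaults, so
#' `dpcnet_config(ranking = list(top_k = 10))` changes one field only.
#'
#' @param preprocess list: `min_expressed_fraction` (strict >, default 0.5),
#'   `presence_threshold` (default 0), `ppi_min_confidence` (strict >,
#'   default 500)
#' @param significance list: `pearson_alpha` (BH, default 0.01),
#'   `partial_alpha` (Bonferroni, default 0.05)
#' @param diff_network list: `meth_score_threshold` (strict >, default 0.7)
#' @param ranking list: `diff_pcorn_min_degree` (strict >, default 30),
#'   `diff_mn_min_degree` (strict >, default 15), `top_k` (default 15)
#' @param exhaustive_k condition partial tests on every gene instead of PCCN
#'   common neighbors (slow; default FALSE)
#' @return list of class `dpcnet_config`
#' @export
dpcnet_config <- function(preprocess = list(), significance = list(),
                          diff_network = list(), ranking = list(),
                          exhaustive_k = FALSE) {
  def <- list(
    preprocess = list(min_expressed_fraction = 0.5, presence_threshold = 0,
                      ppi_min_confidence = 500),
    significance = list(pearson_alpha = 0.01, partial_alpha = 0.05),
    diff_network = list(meth_score_threshold = 0.7),
    ranking = list(diff_pcorn_min_degree = 30, diff_mn_min_degree = 15,
                   top_k = 15),
    exhaustive_k = FALSE
  )
  cfg <- def
  cfg$preprocess <- utils::modifyList(def$preprocess, preprocess)
  cfg$significance <- utils::modifyList(def$significance, significance)
  cfg$diff_network <- utils::modifyList(def$diff_network, diff_network)
  cfg$ranking <- utils::modifyList(def$ranking, ranking)
  cfg$exhaustive_k <- isTRUE(exhaustive_k)
  with(cfg, {
    stopifnot(preprocess$min_expressed_fraction >= 0,
              preprocess$min_expressed_fraction <= 1,
              preprocess$ppi_min_confidence >= 1,
              preprocess$ppi_min_confidence <= 999,
              significance$pearson_alpha > 0, significance$pearson_alpha < 1,
              significance$partial_alpha > 0, significance$partial_alpha < 1,
              diff_network$meth_score_threshold >= 0,
              diff_network$meth_score_threshold <= 2,
              ranking$diff_pcorn_min_degree > 0,
              ranking$diff_mn_min_degree > 0, ranking$top_k > 0)
  })
  structure(cfg, class = "dpcnet_config")
}

#' Fit the differential partial correlation network model
#'
#' Runs the full analysis on an aligned multi-omics dataset:
#' \enumerate{
#'   \item filter genes expressed in more than half of the samples and
#'     methylation sites mapping to a single gene with complete values;
#'   \item background network = PPI edges above the confidence threshold
#'     between expressed genes;
#'   \item per group, Pearson correlation network (PCCN; BH-adjusted
#'     p < `pearson_alpha`) then first-order partial correlation network
#'     (PCORN; Bonferroni-adjusted p < `partial_alpha`, conditioning on the
#'     common neighbor minimizing the absolute partial correlation);
#'   \item Diff-PCORN = symmetric difference of the two PCORNs;
#'   \item Diff-MN = Diff-PCORN edges whose maximal cross-gene site-pair
#'     methylation correlation difference exceeds `meth_score_threshold`;
#'   \item candidates = Diff-PCORN hubs intersected with Diff-MN hubs,
#'     ranked by somatic variation frequency (ties by Diff-PCORN degree,
#'     then lexicographic), top `top_k` selected as the disease module.
#' }
#' Methylation and mutation stages are skipped (with empty results) when
#' the corresponding layer is absent from `data`; without methylation the
#' candidate overlap uses the Diff-PCORN hub set alone.
#'
#' @param data an [omics_dataset()]
#' @param ppi a [gene_network] with `confidence` edge attribute
#' @param config a [dpcnet_config()]
#' @return object of class `dpcnet`: list with `networks` (background,
#'   pccn/pcorn per group, diff_pcorn, diff_mn), `candidates` (a
#'   [rank_candidates()] table), `counts` (per-stage node/edge counts),
#'   `config`, and `labels`
#' @seealso [classify_cv()], [cluster_samples()], [hypergeom_tail()] for
#'   validating a fitted module; [simulate_omics()] for synthetic data
#' @export
dpcnet <- function(data, ppi, config = dpcnet_config()) {
  stopifnot(inherits(data, "omics_dataset"))
  if (!inherits(config, "dpcnet_config"))
    config <- do.call(dpcnet_config, config)
  pp <- config$preprocess
  expr <- filter_expressed_genes(data$expr, pp$min_expressed_fraction,
                                 pp$presence_threshold)
  background <- build_background_network(ppi, expr, pp$ppi_min_confidence)

  sig <- config$significance
  pccn <- lapply(c(tumor = "tumor", normal = "normal"), function(g)
    build_pccn(expr, background, data$labels, g, sig$pearson_alpha))
  pcorn <- lapply(c(tumor = "tumor", normal = "normal"), function(g)
    build_pcorn(pccn[[g]], expr, data$labels, g, sig$partial_alpha,
                exhaustive_k = config$exhaustive_k))
  diff_pcorn <- diff_network(pcorn$tumor, pcorn$normal)

  meth <- NULL
  diff_mn <- gene_network()
  if (!is.null(data$meth)) {
    meth <- filter_methylation_sites(data$meth)
    diff_mn <- build_diff_mn(diff_pcorn, meth, data$labels,
                             config$diff_network$meth_score_threshold)
  }

  rk <- config$ranking
  set1 <- degree_filter(diff_pcorn, rk$diff_pcorn_min_degree)
  set2 <- if (!is.null(data$meth)) degree_filter(diff_mn, rk$diff_mn_min_degree)
          else set1
  freq <- if (!is.null(data$mut))
    variation_frequency(data$mut, genes = union(set1, set2))
  else stats::setNames(numeric(0), character(0))
  candidates <- rank_candidates(set1, set2, freq, diff_pcorn, diff_mn,
                                top_k = rk$top_k)

  counts <- list(
    genes_input = nrow(data$expr), genes_expressed = nrow(expr),
    background_edges = n_edges(background),
    background_nodes = n_nodes(background),
    pccn_tumor_edges = n_edges(pccn$tumor),
    pccn_normal_edges = n_edges(pccn$normal),
    pcorn_tumor_edges = n_edges(pcorn$tumor),
    pcorn_normal_edges = n_edges(pcorn$normal),
    common_pcorn_edges = length(intersect(edge_keys(pcorn$tumor),
                                          edge_keys(pcorn$normal))),
    diff_pcorn_edges = n_edges(diff_pcorn),
    diff_pcorn_nodes = n_nodes(diff_pcorn),
    diff_pcorn_tumor_origin = sum(diff_pcorn$edges$origin == "tumor_only"),
    diff_mn_edges = n_edges(diff_mn), diff_mn_nodes = n_nodes(diff_mn),
    candidate_set1 = length(set1), candidate_set2 = length(set2),
    overlap = nrow(candidates),
    selected = sum(candidates$selected)
  )
  structure(list(networks = c(list(background = background),
                              list(pccn = pccn, pcorn = pcorn,
                                   diff_pcorn = diff_pcorn,
                                   diff_mn = diff_mn)),
                 candidates = candidates, counts = counts,
                 config = config, labels = data$labels),
            class = "dpcnet")
}

#' @export
print.dpcnet <- function(x, ...) {
  ct <- x$counts
  cat("Differential partial correlation network fit\n")
  cat(sprintf("  genes: %d input, %d expressed; background: %d edges / %d nodes\n",
              ct$genes_input, ct$genes_expressed, ct$background_edges,
              ct$background_nodes))
  cat(sprintf("  PCCN  edges: %d tumor, %d normal\n",
              ct$pccn_tumor_edges, ct$pccn_normal_edges))
  cat(sprintf("  PCORN edges: %d tumor, %d normal (%d common)\n",
              ct$pcorn_tumor_edges, ct$pcorn_normal_edges,
              ct$common_pcorn_edges))
  cat(sprintf("  Diff-PCORN: %d edges (%d tumor-origin) / %d nodes\n",
              ct$diff_pcorn_edges, ct$diff_pcorn_tumor_origin,
              ct$diff_pcorn_nodes))
  cat(sprintf("  Diff-MN: %d edges / %d nodes\n",
              ct$diff_mn_edges, ct$diff_mn_nodes))
  cat(sprintf("  candidates: %d hub / %d methylation-hub, %d overlap, %d selected\n",
              ct$candidate_set1, ct$candidate_set2, ct$overlap, ct$selected))
  sel <- attr(x$candidates, "selected")
  if (length(sel))
    cat("  module:", paste(sel, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dpcnet <- function(object, ...) {
  structure(list(counts = object$counts, candidates = object$candidates,
                 config = object$config),
            class = "summary.dpcnet")
}

#' @export
print.summary.dpcnet <- function(x, ...) {
  cat("Stage counts:\n")
  print(data.frame(count = unlist(x$counts)))
  cat("\nRanked candidates:\n")
  print(x$candidates)
  invisible(x)
}

#' Plot a fitted dpcnet object
#'
#' Two base-graphics panels: per-stage edge counts of the network cascade,
#' and the Diff-PCORN degree distribution with the ranking threshold.
#'
#' @param x a [dpcnet] fit
#' @param ... ignored
#' @export
plot.dpcnet <- function(x, ...) {
  ct <- x$counts
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  counts <- c(background = ct$background_edges,
              `PCCN tumor` = ct$pccn_tumor_edges,
              `PCCN normal` = ct$pccn_normal_edges,
              `PCORN tumor` = ct$pcorn_tumor_edges,
              `PCORN normal` = ct$pcorn_normal_edges,
              `Diff-PCORN` = ct$diff_pcorn_edges,
              `Diff-MN` = ct$diff_mn_edges)
  graphics::barplot(counts, las = 2, ylab = "edges",
                    main = "network cascade")
  deg <- network_degree(x$networks$diff_pcorn)
  if (length(deg)) {
    graphics::hist(deg, breaks = 30, main = "Diff-PCORN degree",
                   xlab = "degree", col = "grey")
    graphics::abline(v = x$config$ranking$diff_pcorn_min_degree,
                     lty = 2, col = "red")
  }
  invisible(x)
}
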