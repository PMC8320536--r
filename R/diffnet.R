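#' Differential network: symmetric difference of two group networks
#'
#' An edge is differential when it is present in exactly one of the two
#' networks; each retained edge is tagged with its origin
#' (`tumor_only` / `normal_only`). The node set is the endpoints of the
#' retained edges.
#'
#' @param net_tumor,net_normal [gene_network]s over the same gene universe
#' @return a [gene_network] with edge attribute `origin`
#' @export
diff_network <- function(net_tumor, net_normal) {
  kt <- edge_keys(net_tumor)
  kn <- edge_keys(net_normal)
  t_only <- net_tumor$edges[!(kt %in% kn), c("gene_a", "gene_b"), drop = FALSE]
  n_only <- net_normal$edges[!(kn %in% kt), c("gene_a", "gene_b"), drop = FALSE]
  ed <- rbind(
    if (nrow(t_only)) cbind(t_only, origin = "tumor_only"),
    if (nrow(n_only)) cbind(n_only, origin = "normal_only")
  )
  if (is.null(ed))
    ed <- data.frame(gene_a = character(), gene_b = character(),
                     origin = character(), stringsAsFactors = FALSE)
  gene_network(ed)
}

#' Differential co-methylation score for one gene pair
#'
#' For every cross-gene pair of methylation sites (one site from each gene)
#' the Pearson correlation of Beta values is computed within the tumor
#' samples and within the normal samples; the edge score is the maximum over
#' site pairs of `|r_tumor - r_normal|`, and the argmax site pair is
#' recorded. Site pairs with an undefined correlation in either group
#' (constant site) are skipped.
#'
#' @param pair character vector of two gene symbols
#' @param meth filtered methylation list (`values`, single-gene `site_gene`)
#' @param labels named group factor over the methylation samples
#' @return list with `score`, `best_site_pair` (character of length 2, in
#'   gene order), and `n_site_pairs`; `score` is NA when no site pair is
#'   scoreable
#' @export
edge_methylation_score <- function(pair, meth, labels) {
  stopifnot(length(pair) == 2)
  sites_a <- names(meth$site_gene)[meth$site_gene == pair[1]]
  sites_b <- names(meth$site_gene)[meth$site_gene == pair[2]]
  if (!length(sites_a) || !length(sites_b))
    stop(sprintf("gene %s has no mapped methylation site",
                 if (length(sites_a)) pair[2] else pair[1]))
  st <- group_samples(labels, "tumor")
  sn <- group_samples(labels, "normal")
  st <- intersect(st, colnames(meth$values))
  sn <- intersect(sn, colnames(meth$values))
  Xa <- t(meth$values[sites_a, , drop = FALSE])
  Xb <- t(meth$values[sites_b, , drop = FALSE])
  rt <- suppressWarnings(stats::cor(Xa[st, , drop = FALSE], Xb[st, , drop = FALSE]))
  rn <- suppressWarnings(stats::cor(Xa[sn, , drop = FALSE], Xb[sn, , drop = FALSE]))
  d <- abs(rt - rn)
  if (all(is.na(d)))
    return(list(score = NA_real_, best_site_pair = c(NA, NA),
                n_site_pairs = length(d)))
  best <- which(d == max(d, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(sites_a[best[, 1]], sites_b[best[, 2]]), , drop = FALSE][1, ]
  list(score = max(d, na.rm = TRUE),
       best_site_pair = c(sites_a[best[1]], sites_b[best[2]]),
       n_site_pairs = length(d))
}

#' Differential methylation network (Diff-MN)
#'
#' Scores every differential-network edge whose two genes both have mapped
#' methylation sites with [edge_methylation_score()], and keeps edges whose
#' score is strictly greater than `score_threshold`. Edges lacking
#' methylation coverage on either gene are excluded (their count is
#' reported via [message()]).
#'
#' @param diff_pcorn the differential partial correlation network
#' @param meth filtered methylation list
#' @param labels named group factor over the methylation samples
#' @param score_threshold minimum `max |r_tumor - r_normal|` (strict >),
#'   default 0.7
#' @return a [gene_network] with edge attributes `score`, `site_a`,
#'   `site_b`, `n_site_pairs`
#' @export
build_diff_mn <- function(diff_pcorn, meth, labels, score_threshold = 0.7) {
  ed <- diff_pcorn$edges
  covered_genes <- unique(meth$site_gene)
  cov <- ed$gene_a %in% covered_genes & ed$gene_b %in% covered_genes
  if (any(!cov))
    message(sum(!cov), " edge(s) without methylation coverage skipped")
  ed <- ed[cov, , drop = FALSE]
  if (!nrow(ed)) return(gene_network())
  score <- numeric(nrow(ed))
  site_a <- site_b <- character(nrow(ed))
  npairs <- integer(nrow(ed))
  for (e in seq_len(nrow(ed))) {
    s <- edge_methylation_score(c(ed$gene_a[e], ed$gene_b[e]), meth, labels)
    score[e] <- s$score
    site_a[e] <- s$best_site_pair[1]
    site_b[e] <- s$best_site_pair[2]
    npairs[e] <- s$n_site_pairs
  }
  keep <- !is.na(score) & score > score_threshold
  gene_network(data.frame(gene_a = ed$gene_a, gene_b = ed$gene_b,
                          score = score, site_a = site_a, site_b = site_b,
                          n_site_pairs = npairs,
                          stringsAsFactors = FALSE)[keep, , drop = FALSE])
}
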