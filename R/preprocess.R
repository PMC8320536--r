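#' Keep genes expressed in more than a given fraction of samples
#'
#' A gene is retained when the number of samples in which its value exceeds
#' `presence_threshold` is strictly greater than `min_fraction` of all
#' samples (tumor and normal pooled). With the defaults this is the usual
#' "expressed (FPKM > 0) in more than half of the total samples" rule.
#'
#' @param expr numeric matrix, genes x samples
#' @param min_fraction fraction of samples required (strict >), default 0.5
#' @param presence_threshold value above which a gene counts as expressed in
#'   a sample, default 0
#' @return the filtered matrix (same samples)
#' @export
filter_expressed_genes <- function(expr, min_fraction = 0.5,
                                   presence_threshold = 0) {
  stopifnot(is.matrix(expr), ncol(expr) > 0)
  frac <- rowSums(expr > presence_threshold) / ncol(expr)
  keep <- frac > min_fraction
  if (!any(keep))
    stop("no gene passes the expression filter; lower min_fraction or ",
         "presence_threshold")
  expr[keep, , drop = FALSE]
}

#' Keep methylation sites mapping to exactly one gene with complete values
#'
#' Drops sites whose annotation is missing, empty, or semicolon-separated
#' (multi-gene), and sites whose Beta-value row contains any missing entry.
#' After this filter every retained site maps to a single gene symbol and
#' has no NA.
#'
#' @param meth list with `values` matrix and `site_gene` raw annotation, as
#'   from [read_methylation()]
#' @return list with filtered `values` and resolved single-gene `site_gene`
#' @export
filter_methylation_sites <- function(meth) {
  gene <- meth$site_gene
  single <- !is.na(gene) & nzchar(gene) & !grepl(";", gene, fixed = TRUE)
  complete <- !apply(is.na(meth$values), 1, any)
  keep <- single & complete
  list(values = meth$values[keep, , drop = FALSE],
       site_gene = gene[keep])
}

#' Build the background interaction network
#'
#' Keeps PPI edges whose confidence is strictly greater than
#' `min_confidence` and whose two endpoints are both present in the
#' (already expression-filtered) matrix; nodes left without edges are
#' removed.
#'
#' @param ppi a [gene_network] with `confidence` edge attribute
#' @param expr filtered expression matrix (rownames define the gene universe)
#' @param min_confidence STRING combined-score threshold (strict >), default 500
#' @return a [gene_network]
#' @export
build_background_network <- function(ppi, expr, min_confidence = 500) {
  genes <- rownames(expr)
  ed <- ppi$edges
  keep <- ed$confidence > min_confidence &
    ed$gene_a %in% genes & ed$gene_b %in% genes
  ed <- ed[keep, , drop = FALSE]
  if (!nrow(ed))
    stop("background network is empty; lower min_confidence or check that ",
         "PPI identifiers match expression gene symbols")
  gene_network(ed)
}
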