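# samples belonging to one group, with the >= 3 guard shared by all builders
group_samples <- function(labels, group, min_n = 3) {
  group <- match.arg(group, c("tumor", "normal"))
  s <- names(labels)[labels == group]
  if (length(s) < min_n)
    stop(sprintf("group '%s' has %d sample(s); need at least %d",
                 group, length(s), min_n))
  s
}

# gene x gene Pearson correlation matrix on one group's samples;
# constant genes yield NA rows/columns (handled downstream as p = 1)
group_cor_matrix <- function(expr, genes, samples) {
  X <- t(expr[genes, samples, drop = FALSE])
  suppressWarnings(stats::cor(X))
}

#' Per-group Pearson correlation network (PCCN)
#'
#' For every background edge, computes the Pearson correlation of the two
#' genes over the chosen group's samples, adjusts the p-values jointly over
#' all background edges with Benjamini-Hochberg, and keeps edges with
#' adjusted p strictly below `pearson_alpha`. Edges with an undefined
#' correlation (constant gene) are assigned p = 1 with a warning and are
#' never kept.
#'
#' @param expr filtered expression matrix (genes x samples)
#' @param background a [gene_network] over the expression genes
#' @param labels named group factor as in [omics_dataset()]
#' @param group `"tumor"` or `"normal"`
#' @param pearson_alpha BH-adjusted significance cutoff (strict <), default 0.01
#' @return a [gene_network] with edge attributes `r`, `p`, `p_adj`; nodes
#'   are the endpoints of retained edges
#' @export
build_pccn <- function(expr, background, labels, group, pearson_alpha = 0.01) {
  samp <- group_samples(labels, group)
  ed <- background$edges
  if (!nrow(ed)) return(gene_network())
  genes <- sort(unique(c(ed$gene_a, ed$gene_b)))
  genes <- intersect(genes, rownames(expr))
  ed <- ed[ed$gene_a %in% genes & ed$gene_b %in% genes, , drop = FALSE]
  if (!nrow(ed)) return(gene_network())
  R <- group_cor_matrix(expr, genes, samp)
  r <- R[cbind(match(ed$gene_a, genes), match(ed$gene_b, genes))]
  if (anyNA(r))
    warning(sum(is.na(r)),
            " edge(s) with undefined correlation (constant gene); p set to 1")
  p <- r_to_p(r, df = length(samp) - 2)
  p_adj <- bh_adjust(p)
  keep <- p_adj < pearson_alpha
  gene_network(data.frame(gene_a = ed$gene_a, gene_b = ed$gene_b,
                          r = r, p = p, p_adj = p_adj,
                          stringsAsFactors = FALSE)[keep, , drop = FALSE])
}

# adjacency list of a network restricted to `genes`, each entry sorted
adjacency_list <- function(net) {
  ed <- net$edges
  adj <- split(c(ed$gene_b, ed$gene_a), c(ed$gene_a, ed$gene_b))
  lapply(adj, sort)
}

# core of the PCORN edge test, vectorised over the edges of a PCCN.
# For each edge (i, j): conditioning candidates are PCCN common neighbors;
# the candidate minimizing |r_ij(k)| is tested (an edge survives only when
# no single neighbor explains it away); ties break lexicographically on k.
# With no usable candidate the zero-order r is tested (q = 0).
partial_edge_stats <- function(pccn, R, genes, n_samples,
                               exhaustive_k = FALSE) {
  ed <- pccn$edges
  m <- nrow(ed)
  out <- data.frame(gene_a = ed$gene_a, gene_b = ed$gene_b,
                    r = NA_real_, r_partial = NA_real_,
                    k_selected = NA_character_, order = 0L,
                    t = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  if (!m) return(out)
  adj <- adjacency_list(pccn)
  ia <- match(ed$gene_a, genes)
  ib <- match(ed$gene_b, genes)
  out$r <- R[cbind(ia, ib)]
  for (e in seq_len(m)) {
    a <- ed$gene_a[e]; b <- ed$gene_b[e]
    cand <- if (exhaustive_k) setdiff(genes, c(a, b))
            else setdiff(intersect(adj[[a]], adj[[b]]), c(a, b))
    r_ij <- out$r[e]
    rp <- r_ij; ks <- NA_character_; q <- 0L
    if (length(cand) && !is.na(r_ij)) {
      ik <- match(cand, genes)
      part <- first_order_partial(r_ij, R[ia[e], ik], R[ib[e], ik])
      ok <- !is.na(part)
      if (any(ok)) {
        part <- part[ok]; candk <- cand[ok]
        best <- which.min(abs(part))   # cand sorted: ties -> lexicographic k
        rp <- part[best]; ks <- candk[best]; q <- 1L
      } else {
        warning(sprintf("edge %s-%s: all conditioning candidates degenerate; %s",
                        a, b, "falling back to order 0"))
      }
    }
    out$r_partial[e] <- rp
    out$k_selected[e] <- ks
    out$order[e] <- q
  }
  const <- is.na(out$r_partial)
  ok <- !const
  df <- n_samples - out$order - 2
  out$t[ok] <- out$r_partial[ok] * sqrt(df[ok]) /
    sqrt(pmax(1 - out$r_partial[ok]^2, 0))
  out$p <- ifelse(const, 1,
                  ifelse(abs(out$r_partial) >= 1, 0,
                         2 * stats::pt(abs(out$t), df = df, lower.tail = FALSE)))
  out
}

#' First-order partial correlation test for one PCCN edge
#'
#' Conditioning candidates are the genes adjacent to both endpoints in the
#' PCCN (common neighbors). For each candidate k the first-order partial
#' correlation is computed from the group's pairwise Pearson correlations,
#' and the candidate minimizing `|r_ij(k)|` is tested — the most
#' conservative choice, so an edge survives only if no single network
#' neighbor explains it away. Without a common neighbor the zero-order
#' correlation is tested (order 0).
#'
#' @param pair character vector of two gene symbols (must be a PCCN edge)
#' @param pccn the group's PCCN [gene_network]
#' @param expr filtered expression matrix
#' @param labels named group factor
#' @param group `"tumor"` or `"normal"`
#' @param exhaustive_k if TRUE, condition on every other PCCN gene instead
#'   of common neighbors only
#' @return one-row data.frame with `r`, `r_partial`, `k_selected`, `order`,
#'   `t`, `p`
#' @export
edge_partial_test <- function(pair, pccn, expr, labels, group,
                              exhaustive_k = FALSE) {
  stopifnot(length(pair) == 2)
  if (!has_edge(pccn, pair[1], pair[2]))
    stop(sprintf("%s-%s is not a PCCN edge", pair[1], pair[2]))
  samp <- group_samples(labels, group)
  genes <- intersect(pccn$nodes, rownames(expr))
  R <- group_cor_matrix(expr, genes, samp)
  stats <- partial_edge_stats(pccn, R, genes, length(samp),
                              exhaustive_k = exhaustive_k)
  key <- pair_key(pair[1], pair[2])
  stats[pair_key(stats$gene_a, stats$gene_b) == key, , drop = FALSE]
}

#' Per-group first-order partial correlation network (PCORN)
#'
#' Runs the [edge_partial_test()] rule for every PCCN edge, adjusts the
#' resulting p-values jointly over all PCCN edges of the group with
#' Bonferroni, and keeps edges with adjusted p strictly below
#' `partial_alpha`.
#'
#' @inheritParams edge_partial_test
#' @param partial_alpha Bonferroni-adjusted cutoff (strict <), default 0.05
#' @return a [gene_network] with edge attributes `r`, `r_partial`,
#'   `k_selected`, `order`, `t`, `p`, `p_adj`
#' @export
build_pcorn <- function(pccn, expr, labels, group, partial_alpha = 0.05,
                        exhaustive_k = FALSE) {
  if (!n_edges(pccn)) return(gene_network())
  samp <- group_samples(labels, group)
  genes <- intersect(pccn$nodes, rownames(expr))
  R <- group_cor_matrix(expr, genes, samp)
  stats <- partial_edge_stats(pccn, R, genes, length(samp),
                              exhaustive_k = exhaustive_k)
  stats$p_adj <- bonferroni_adjust(stats$p)
  gene_network(stats[stats$p_adj < partial_alpha, , drop = FALSE])
}
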