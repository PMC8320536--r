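#' Undirected gene network
#'
#' Lightweight container for an undirected network over gene symbols. Edges
#' are stored in canonical form (`gene_a < gene_b` lexicographically, rows
#' sorted) so that edge identity is order-invariant and all written edge
#' lists are reproducible. Self-loops are dropped; duplicate edges keep the
#' first occurrence (readers that need a different collapse rule, e.g.
#' keep-max confidence, resolve duplicates before construction).
#'
#' @param edges data.frame with character columns `gene_a`, `gene_b` plus
#'   arbitrary edge-attribute columns (confidence, r, p, p_adj, origin, ...).
#' @param nodes optional character vector of node names to keep even when
#'   isolated; edge endpoints are always included.
#' @return object of class `gene_network`: list with elements `edges`
#'   (canonical data.frame) and `nodes` (sorted character vector).
#' @examples
#' net <- gene_network(data.frame(gene_a = c("B", "A"), gene_b = c("A", "C")))
#' has_edge(net, "A", "B")
#' @export
gene_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b") %in% names(edges)))
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  swap <- edges$gene_a > edges$gene_b
  if (any(swap)) {
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
  }
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(as.character(nodes), edges$gene_a, edges$gene_b)))
  structure(list(edges = edges, nodes = nodes), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  attrs <- setdiff(names(x$edges), c("gene_a", "gene_b"))
  if (length(attrs)) cat("edge attributes:", paste(attrs, collapse = ", "), "\n")
  invisible(x)
}

#' Number of edges / nodes in a gene network
#' @param net a `gene_network`
#' @return integer count
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) length(net$nodes)

# canonical edge keys, used for set operations between networks
edge_keys <- function(net) paste(net$edges$gene_a, net$edges$gene_b, sep = "\r")

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Test edge membership (order-invariant)
#' @param net a `gene_network`
#' @param a,b gene symbols (vectorised)
#' @return logical vector
#' @export
has_edge <- function(net, a, b) pair_key(a, b) %in% edge_keys(net)

#' Node degrees of a gene network
#' @param net a `gene_network`
#' @return named integer vector over all nodes (isolated nodes get 0)
#' @export
network_degree <- function(net) {
  deg <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                      levels = net$nodes))
  stats::setNames(as.integer(deg), names(deg))
}

#' Write / read a gene network as a TSV edge list
#'
#' Columns are `gene_a`, `gene_b`, then edge attributes; rows are in
#' canonical sorted order so a write/read round trip is the identity.
#'
#' @param net a `gene_network`
#' @param path file path
#' @return `write_network` returns `path` invisibly; `read_network` a
#'   `gene_network`.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  if (nrow(ed)) {
    ed$gene_a <- as.character(ed$gene_a)
    ed$gene_b <- as.character(ed$gene_b)
  }
  gene_network(ed)
}
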