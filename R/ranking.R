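#' Genes exceeding a degree threshold
#'
#' @param net a [gene_network]
#' @param min_degree keep genes with degree strictly greater than this
#' @return sorted character vector of gene symbols
#' @export
degree_filter <- function(net, min_degree) {
  deg <- network_degree(net)
  sort(names(deg)[deg > min_degree])
}

#' Per-gene somatic variation frequency
#'
#' For each gene, the number of distinct samples in which it carries at
#' least one variant divided by the total number of samples in the variant
#' data. Genes absent from the records have frequency 0 (use the `genes`
#' argument to materialise them).
#'
#' @param mut mutation list (`records`, `sample_universe`) as from
#'   [read_mutations()]
#' @param genes optional gene universe to report (defaults to mutated genes)
#' @return named numeric vector of frequencies in \[0, 1\]
#' @export
variation_frequency <- function(mut, genes = NULL) {
  if (!length(mut$sample_universe))
    stop("mutation table has an empty sample universe")
  counts <- tapply(mut$records$sample, mut$records$gene,
                   function(s) length(unique(s)))
  freq <- counts / length(mut$sample_universe)
  if (is.null(genes)) genes <- sort(names(freq))
  out <- stats::setNames(rep(0, length(genes)), genes)
  hit <- intersect(genes, names(freq))
  out[hit] <- freq[hit]
  out
}

#' Rank candidate disease genes by variation frequency
#'
#' Takes the overlap of the two candidate sets (hub genes of the
#' differential partial-correlation network and of the differential
#' methylation network) and orders it by descending variation frequency,
#' breaking ties by descending Diff-PCORN degree and remaining ties
#' lexicographically. The first `top_k` genes are the selected module
#' biomarkers.
#'
#' @param set1 hub genes of the Diff-PCORN (first candidate set)
#' @param set2 hub genes of the Diff-MN (second candidate set)
#' @param freq named variation-frequency vector; overlap genes missing from
#'   it get frequency 0
#' @param diff_pcorn the differential partial correlation network (degrees
#'   used for the tie-break and the report)
#' @param diff_mn optional differential methylation network (degrees
#'   reported when given)
#' @param top_k number of genes to select, default 15
#' @return data.frame of class `ranked_candidates` with columns `rank`,
#'   `gene`, `variation_frequency`, `diff_pcorn_degree`, `diff_mn_degree`,
#'   `selected`; attribute `selected` holds the chosen gene vector
#' @export
rank_candidates <- function(set1, set2, freq, diff_pcorn, diff_mn = NULL,
                            top_k = 15) {
  overlap <- sort(intersect(set1, set2))
  if (!length(overlap)) {
    warning("empty overlap between the two candidate gene sets")
    out <- data.frame(rank = integer(), gene = character(),
                      variation_frequency = numeric(),
                      diff_pcorn_degree = integer(),
                      diff_mn_degree = integer(), selected = logical())
    attr(out, "selected") <- character()
    class(out) <- c("ranked_candidates", "data.frame")
    return(out)
  }
  f <- stats::setNames(rep(0, length(overlap)), overlap)
  hit <- intersect(overlap, names(freq))
  f[hit] <- freq[hit]
  deg1 <- network_degree(diff_pcorn)
  d1 <- ifelse(overlap %in% names(deg1), deg1[overlap], 0L)
  d2 <- if (!is.null(diff_mn)) {
    deg2 <- network_degree(diff_mn)
    ifelse(overlap %in% names(deg2), deg2[overlap], 0L)
  } else rep(NA_integer_, length(overlap))
  ord <- order(-f, -d1, overlap)
  out <- data.frame(rank = seq_along(overlap),
                    gene = overlap[ord],
                    variation_frequency = unname(f[ord]),
                    diff_pcorn_degree = as.integer(d1[ord]),
                    diff_mn_degree = as.integer(d2[ord]),
                    stringsAsFactors = FALSE)
  out$selected <- out$rank <= top_k
  attr(out, "selected") <- out$gene[out$selected]
  class(out) <- c("ranked_candidates", "data.frame")
  out
}

#' @export
print.ranked_candidates <- function(x, ...) {
  cat(sprintf("ranked_candidates: %d overlap gene(s), %d selected\n",
              nrow(x), sum(x$selected)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20))
  invisible(x)
}
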