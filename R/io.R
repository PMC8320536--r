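#' Read a gene-expression matrix and its sample-group labels
#'
#' Expression input is a tab-separated matrix: first column gene symbols,
#' header row sample ids, FPKM-scale non-negative values. The label file is
#' tab-separated with columns `sample_id` and `group` (`tumor` / `normal`)
#' and must cover every sample column exactly once.
#'
#' Duplicate gene symbols keep the row with the highest mean expression (a
#' warning reports how many rows were dropped).
#'
#' @param path expression matrix file
#' @param label_path sample annotation file
#' @param barcode_prefix optional integer; when > 0, sample ids in both files
#'   are truncated to this many leading characters before matching (useful
#'   for TCGA-style barcodes that differ by assay-specific suffixes).
#'   Default 0 = exact matching.
#' @return list with elements `expr` (numeric matrix, genes x samples) and
#'   `labels` (factor with levels `normal`, `tumor`, named by sample id).
#' @export
read_expression <- function(path, label_path, barcode_prefix = 0L) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2) stop("expression file needs a gene column plus >=1 sample column")
  genes <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1]
      stop(sprintf("non-numeric expression value at row '%s', column '%s'",
                   genes[bad], names(vals)[j]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    means <- rowMeans(m)
    ord <- order(-means)        # highest-mean row wins within each symbol
    keep <- ord[!duplicated(genes[ord])]
    dropped <- nrow(m) - length(keep)
    warning(sprintf("%d duplicate gene row(s) dropped (kept highest mean)",
                    dropped))
    m <- m[sort(keep), , drop = FALSE]
  }
  labels <- read_labels(label_path)
  cols <- colnames(m)
  if (barcode_prefix > 0) {
    cols <- substr(cols, 1, barcode_prefix)
    names(labels) <- substr(names(labels), 1, barcode_prefix)
    labels <- labels[!duplicated(names(labels))]
    colnames(m) <- cols
  }
  unknown <- setdiff(names(labels), cols)
  if (length(unknown))
    stop("label file contains sample(s) not in the expression matrix: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(cols, names(labels))
  if (length(missing))
    stop("label file is missing sample(s): ", paste(missing, collapse = ", "))
  list(expr = m, labels = labels[cols])
}

#' Read a sample-group label file
#'
#' @param path TSV with columns `sample_id`, `group`
#' @return factor with levels `normal`, `tumor`, named by sample id
#' @export
read_labels <- function(path) {
  lab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(lab)))
    stop("label file needs columns 'sample_id' and 'group'")
  bad <- setdiff(unique(lab$group), c("tumor", "normal"))
  if (length(bad))
    stop("unknown group value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(lab$sample_id))
    stop("duplicated sample id(s) in label file")
  stats::setNames(factor(lab$group, levels = c("normal", "tumor")),
                  lab$sample_id)
}

#' Read a STRING-style protein-protein interaction edge list
#'
#' Whitespace-separated rows `protein1 protein2 combined_score` (header
#' optional), scores integer in 1-999. Reciprocal duplicates collapse to a
#' single undirected edge keeping the maximum score; self-loops are dropped.
#' An optional mapping table (TSV, columns `protein`, `symbol`) converts
#' identifiers to gene symbols; edges with an unmappable endpoint are
#' dropped and the count reported via [message()].
#'
#' @param path edge list file
#' @param mapping_path optional identifier-to-symbol table
#' @return a [gene_network] with edge attribute `confidence`
#' @export
read_ppi <- function(path, mapping_path = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", strsplit(trimws(first), "[ \t]+")[[1]][3])
  ed <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(ed) < 3) stop("PPI file needs columns: id_a, id_b, combined_score")
  ed <- ed[, 1:3]
  names(ed) <- c("gene_a", "gene_b", "confidence")
  ed$gene_a <- as.character(ed$gene_a)
  ed$gene_b <- as.character(ed$gene_b)
  if (!is.numeric(ed$confidence) ||
      any(ed$confidence < 1 | ed$confidence > 999 |
            ed$confidence != round(ed$confidence)))
    stop("combined_score must be an integer in [1, 999]")
  if (!is.null(mapping_path)) {
    map <- utils::read.delim(mapping_path, stringsAsFactors = FALSE)
    if (!all(c("protein", "symbol") %in% names(map)))
      stop("mapping file needs columns 'protein' and 'symbol'")
    sym <- stats::setNames(map$symbol, map$protein)
    a <- sym[ed$gene_a]; b <- sym[ed$gene_b]
    ok <- !is.na(a) & !is.na(b)
    if (any(!ok))
      message(sum(!ok), " edge(s) dropped: unmappable identifier")
    ed <- data.frame(gene_a = unname(a[ok]), gene_b = unname(b[ok]),
                     confidence = ed$confidence[ok],
                     stringsAsFactors = FALSE)
  }
  ed <- ed[ed$gene_a != ed$gene_b, , drop = FALSE]
  if (nrow(ed)) {
    key <- pair_key(ed$gene_a, ed$gene_b)
    mx <- tapply(ed$confidence, key, max)
    ed <- ed[!duplicated(key), , drop = FALSE]
    ed$confidence <- as.integer(mx[pair_key(ed$gene_a, ed$gene_b)])
  }
  gene_network(ed)
}

#' Read a methylation Beta-value matrix and its site annotation
#'
#' The matrix file is tab-separated, first column CpG site id, header row
#' sample ids, values Beta in \[0,1\] or missing (`NA`). The annotation maps
#' each site to a gene string, possibly semicolon-separated when a site
#' overlaps several genes; the raw string is preserved verbatim so that
#' [filter_methylation_sites()] can apply the multi-gene filter.
#'
#' @param path matrix file
#' @param annotation_path TSV with columns `site`, `gene`
#' @return list with `values` (numeric matrix, sites x samples, may contain
#'   NA) and `site_gene` (named character vector of raw gene strings)
#' @export
read_methylation <- function(path, annotation_path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sites <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- sites
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("Beta value outside [0,1] at site '%s', sample '%s'",
                 sites[bad[1, 1]], colnames(m)[bad[1, 2]]))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (!all(c("site", "gene") %in% names(ann)))
    stop("annotation file needs columns 'site' and 'gene'")
  site_gene <- stats::setNames(as.character(ann$gene), ann$site)
  list(values = m, site_gene = site_gene[rownames(m)])
}

#' Read a MAF-like somatic mutation table
#'
#' One row per variant; only the gene-symbol and sample-barcode columns are
#' used. Multiple variants of one gene in one sample collapse to a single
#' (gene, sample) record: a gene counts as mutated in a sample when it
#' carries at least one variant there.
#'
#' @param path TSV variant table
#' @param gene_col,sample_col column names (MAF defaults)
#' @return list with `records` (data.frame `gene`, `sample`, one row per
#'   mutated gene-sample pair) and `sample_universe` (distinct barcodes in
#'   the file)
#' @export
read_mutations <- function(path, gene_col = "Hugo_Symbol",
                           sample_col = "Tumor_Sample_Barcode") {
  maf <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(gene_col, sample_col)
  absent <- setdiff(need, names(maf))
  if (length(absent))
    stop("mutation table is missing required column(s): ",
         paste(absent, collapse = ", "))
  rec <- unique(data.frame(gene = as.character(maf[[gene_col]]),
                           sample = as.character(maf[[sample_col]]),
                           stringsAsFactors = FALSE))
  rec <- rec[order(rec$gene, rec$sample), , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, sample_universe = sort(unique(rec$sample)))
}

#' Bundle aligned multi-omics inputs
#'
#' Convenience constructor checking mutual consistency of the layers before
#' fitting. Both groups must be non-empty; methylation and mutation layers
#' are optional (NULL disables the corresponding pipeline stages).
#'
#' @param expr numeric matrix, genes x samples
#' @param labels named factor (`normal` / `tumor`) covering all columns
#' @param meth optional list as returned by [read_methylation()]
#' @param mut optional list as returned by [read_mutations()]
#' @return object of class `omics_dataset`
#' @export
omics_dataset <- function(expr, labels, meth = NULL, mut = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (anyDuplicated(rownames(expr))) stop("duplicate gene symbols in expression matrix")
  if (any(expr < 0)) stop("expression values must be non-negative")
  missing <- setdiff(colnames(expr), names(labels))
  if (length(missing))
    stop("labels missing for sample(s): ", paste(missing, collapse = ", "))
  labels <- droplevels(factor(labels[colnames(expr)],
                              levels = c("normal", "tumor")))
  names(labels) <- colnames(expr)
  if (nlevels(labels) < 2 || any(table(labels) == 0))
    stop("both tumor and normal groups must be non-empty")
  structure(list(expr = expr, labels = labels, meth = meth, mut = mut),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$labels == "tumor"), sum(x$labels == "normal")))
  if (!is.null(x$meth))
    cat(sprintf("  methylation: %d sites\n", nrow(x$meth$values)))
  if (!is.null(x$mut))
    cat(sprintf("  mutations: %d gene-sample records over %d samples\n",
                nrow(x$mut$records), length(x$mut$sample_universe)))
  invisible(x)
}
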