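# fixture builders shared across test files; everything is generated in code

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# tiny expression matrix + matching label file on disk
toy_expression_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                 genes = c("TP53", "EP300", "BPTF"),
                                 samples = c("S1", "S2", "S3", "S4"),
                                 values = NULL,
                                 groups = c("tumor", "tumor", "normal", "normal")) {
  if (is.null(values)) {
    values <- matrix(seq_len(length(genes) * length(samples)),
                     nrow = length(genes), dimnames = list(genes, samples))
  }
  expr_path <- file.path(dir, "expr.tsv")
  write_tsv(data.frame(gene = rownames(values), values, check.names = FALSE),
            expr_path)
  label_path <- file.path(dir, "labels.tsv")
  write_tsv(data.frame(sample_id = samples, group = groups), label_path)
  list(expr = expr_path, labels = label_path, dir = dir)
}

# hand-rolled Benjamini-Hochberg step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

bonferroni_oracle <- function(p) pmin(1, p * length(p))

# brute-force residual-correlation oracle for the first-order partial
residual_partial_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# exact hypergeometric upper tail by enumerating all size-n subsets (N <= 12)
hypergeom_enum_oracle <- function(N, M, n, x) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= M) >= x   # the first M elements are "known" genes
  sum(hits) / ncol(subsets)
}

# Mann-Whitney rank AUC, independent of pROC
auc_rank_oracle <- function(scores, y, positive = "tumor") {
  pos <- y == positive
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

# two-group expression with a mean shift on a subset of genes (separable case)
shifted_expression <- function(n_genes = 20, n_shift = 5, n_tumor = 30,
                               n_normal = 30, shift = 3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- c(sprintf("t%02d", seq_len(n_tumor)),
               sprintf("n%02d", seq_len(n_normal)))
  m <- matrix(stats::rnorm(n_genes * length(samples), mean = 5),
              n_genes, dimnames = list(genes, samples))
  m[seq_len(n_shift), seq_len(n_tumor)] <-
    m[seq_len(n_shift), seq_len(n_tumor)] + shift
  labels <- stats::setNames(
    factor(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
           levels = c("normal", "tumor")), samples)
  list(expr = pmax(m, 0), labels = labels, shifted = genes[seq_len(n_shift)])
}
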