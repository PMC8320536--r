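#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least `x` known disease genes among `n`
#' predicted genes when `M` of the `N` universe genes are known disease
#' genes, computed as the complement of the lower sum
#' `P(X >= x) = 1 - sum_{k=0}^{x-1} C(M,k) C(N-M,n-k) / C(N,n)`
#' with each term evaluated in log space for numerical stability.
#'
#' @param N universe size (total genes)
#' @param M number of known disease genes in the universe
#' @param n number of predicted genes
#' @param x observed overlap
#' @return the tail probability in \[0, 1\]
#' @export
hypergeom_tail <- function(N, M, n, x) {
  stopifnot(N >= 0, M >= 0, n >= 0, x >= 0, M <= N, n <= N)
  if (x > min(M, n))
    stop("infeasible overlap: x must be <= min(M, n)")
  if (x == 0) return(1)
  k <- 0:(x - 1)
  ok <- (n - k) <= (N - M) & (n - k) >= 0
  lt <- lchoose(M, k[ok]) + lchoose(N - M, n - k[ok]) - lchoose(N, n)
  min(1, max(0, 1 - sum(exp(lt))))
}

# stratified fold assignment: every class is spread as evenly as possible
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    if (length(idx) < folds)
      stop(sprintf("class '%s' has fewer samples (%d) than folds (%d); %s",
                   cl, length(idx), folds, "use fewer folds"))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated SVM classification of tumor vs normal samples
#'
#' Stratified k-fold cross-validation of a linear-kernel support vector
#' machine on the expression of a gene subset. The minority class is
#' randomly oversampled (with replacement, to class balance) inside each
#' training fold only, so no test information leaks into training. The ROC
#' curve and AUC are computed from the pooled out-of-fold decision scores.
#'
#' @param expr expression matrix (genes x samples)
#' @param gene_subset genes used as features (must be rows of `expr`)
#' @param labels named group factor over the samples
#' @param folds number of CV folds, default 5
#' @param oversample oversample the minority training class, default TRUE
#' @param seed RNG seed for fold assignment and oversampling
#' @return object of class `classification_report`: list with `auc`,
#'   `fold_count`, `roc_points` (data.frame `fpr`, `tpr`), `oversampled`,
#'   and `scores` (pooled out-of-fold decision values, named by sample)
#' @export
classify_cv <- function(expr, gene_subset, labels, folds = 5,
                        oversample = TRUE, seed = 1) {
  missing <- setdiff(gene_subset, rownames(expr))
  if (length(missing))
    stop("gene(s) not in expression matrix: ", paste(missing, collapse = ", "))
  labels <- droplevels(labels[colnames(expr)])
  if (nlevels(labels) < 2) stop("both classes must be present")
  X <- t(expr[gene_subset, , drop = FALSE])
  y <- factor(as.character(labels), levels = c("normal", "tumor"))
  # seed locally: restore the caller's RNG state on exit
  if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    stats::runif(1)
  old_seed <- get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  set.seed(seed)
  fold <- stratified_folds(y, folds)
  scores <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    ytr <- y[tr]
    if (oversample) {
      tab <- table(ytr)
      minority <- names(tab)[which.min(tab)]
      extra <- sample(tr[ytr == minority], max(tab) - min(tab), replace = TRUE)
      tr <- c(tr, extra)
      ytr <- y[tr]
    }
    Xtr <- X[tr, , drop = FALSE]
    scale_cols <- apply(Xtr, 2, stats::sd) > 0
    fit <- e1071::svm(Xtr, ytr, kernel = "linear", scale = scale_cols)
    pr <- stats::predict(fit, X[te, , drop = FALSE], decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient decision values so that larger = more tumor-like
    pos_first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    scores[te] <- if (pos_first == "tumor") dv[, 1] else -dv[, 1]
  }
  roc <- pROC::roc(response = y, predictor = scores,
                   levels = c("normal", "tumor"), direction = "<",
                   quiet = TRUE)
  pts <- data.frame(fpr = 1 - roc$specificities, tpr = roc$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(auc = as.numeric(pROC::auc(roc)),
                 fold_count = folds,
                 roc_points = pts,
                 oversampled = oversample,
                 scores = stats::setNames(scores, rownames(X))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: AUC %.4f (%d-fold CV%s)\n",
              x$auc, x$fold_count,
              if (x$oversampled) ", oversampled training folds" else ""))
  invisible(x)
}

#' Hierarchical clustering of samples on a gene subset
#'
#' Agglomerative single-linkage clustering with cityblock (L1 / Manhattan)
#' distance over samples, using the expression of the gene subset; the tree
#' is cut at two clusters. The cluster containing the larger share of the
#' true normal samples is called the normal cluster, and
#' `normal_cluster_recall` is the fraction of all normal samples that fall
#' into it.
#'
#' @inheritParams classify_cv
#' @return object of class `clustering_report`: list with `linkage`,
#'   `metric`, `cluster_assignment` (named integer vector),
#'   `normal_cluster`, `normal_cluster_recall`, and `hclust` (the tree)
#' @export
cluster_samples <- function(expr, gene_subset, labels) {
  stopifnot(length(gene_subset) >= 1)
  if (ncol(expr) < 2) stop("need at least 2 samples to cluster")
  X <- t(expr[gene_subset, , drop = FALSE])
  d <- stats::dist(X, method = "manhattan")
  if (all(d == 0))
    warning("all pairwise distances are zero; clustering is degenerate")
  hc <- stats::hclust(d, method = "single")
  cl <- stats::cutree(hc, k = 2)
  labels <- labels[colnames(expr)]
  normals <- names(labels)[labels == "normal"]
  in_cl <- table(factor(cl[normals], levels = c(1, 2)))
  normal_cluster <- as.integer(names(in_cl)[which.max(in_cl)])
  recall <- max(in_cl) / length(normals)
  structure(list(linkage = "single", metric = "cityblock",
                 cluster_assignment = cl,
                 normal_cluster = normal_cluster,
                 normal_cluster_recall = as.numeric(recall),
                 hclust = hc),
            class = "clustering_report")
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf(
    "clustering_report: %s linkage, %s distance; normal-cluster recall %.3f\n",
    x$linkage, x$metric, x$normal_cluster_recall))
  invisible(x)
}

#' Per-gene differential expression t-tests
#'
#' Two-sided Welch two-sample t-test of tumor vs normal expression for each
#' gene in the subset.
#'
#' @inheritParams classify_cv
#' @return data.frame with columns `gene`, `t`, `p`, `direction` (`up` when
#'   the tumor mean is higher)
#' @export
per_gene_differential_test <- function(expr, gene_subset, labels) {
  labels <- labels[colnames(expr)]
  st <- names(labels)[labels == "tumor"]
  sn <- names(labels)[labels == "normal"]
  stopifnot(length(st) >= 2, length(sn) >= 2)
  res <- lapply(gene_subset, function(g) {
    tt <- stats::t.test(expr[g, st], expr[g, sn])
    data.frame(gene = g, t = unname(tt$statistic), p = tt$p.value,
               direction = if (tt$estimate[1] > tt$estimate[2]) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
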