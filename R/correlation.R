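#' Pearson correlation with Student-t p-value
#'
#' Computes Pearson's r and the two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on Student's t with n - 2 degrees
#' of freedom. `|r| = 1` gives p = 0. A constant vector leaves r undefined;
#' the pair is then treated as non-significant (r = NA, p = 1) with a
#' warning, so that such edges simply never enter a network.
#'
#' @param x,y numeric vectors of equal length, n >= 3
#' @return list with elements `r` and `p`
#' @export
pearson_r_p <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined, treated as non-significant")
    return(list(r = NA_real_, p = 1))
  }
  r <- stats::cor(x, y)
  list(r = r, p = r_to_p(r, n - 2))
}

# two-sided p for a correlation-type statistic at the given residual df
r_to_p <- function(r, df) {
  p <- numeric(length(r))
  exact <- !is.na(r) & abs(r) >= 1
  p[exact] <- 0
  ok <- !is.na(r) & !exact
  t <- r[ok] * sqrt(df) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  p[is.na(r)] <- 1
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, capped at 1 and
#' returned in the input order.
#'
#' @param p numeric vector of p-values in \[0,1\]
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjusted p-values
#'
#' `min(1, m * p)` with m the number of tests.
#'
#' @param p numeric vector of p-values in \[0,1\]
#' @return adjusted p-values
#' @export
bonferroni_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "bonferroni")
}

#' First-order partial correlation
#'
#' Correlation of genes i and j after removing the linear effect of a single
#' conditioning gene k:
#' `r_ij(k) = (r_ij - r_ik * r_jk) / (sqrt(1 - r_ik^2) * sqrt(1 - r_jk^2))`.
#' The result is clamped to \[-1, 1\] against floating-point overshoot.
#' When `|r_ik| = 1` or `|r_jk| = 1` the quantity is undefined (degenerate
#' conditioning) and NA is returned so the caller can skip that k.
#'
#' @param r_ij,r_ik,r_jk pairwise Pearson correlations (vectorised over k)
#' @return partial correlation(s) in \[-1, 1\], NA where degenerate
#' @export
first_order_partial <- function(r_ij, r_ik, r_jk) {
  stopifnot(all(abs(c(r_ij, r_ik, r_jk)) <= 1 + 1e-12, na.rm = TRUE))
  den2 <- (1 - r_ik^2) * (1 - r_jk^2)
  out <- ifelse(den2 <= 0, NA_real_, (r_ij - r_ik * r_jk) / sqrt(pmax(den2, 0)))
  pmin(1, pmax(-1, out))
}

#' t statistic and p-value for a (partial) correlation
#'
#' `t = r * sqrt(N - q - 2) / sqrt(1 - r^2)` where N is the sample size and
#' q the order of the partial correlation (0 for a plain Pearson r, 1 after
#' conditioning on one gene); the two-sided p-value comes from Student's t
#' with N - q - 2 degrees of freedom. `|r| = 1` gives t = +/-Inf, p = 0.
#'
#' @param r_partial (partial) correlation in \[-1, 1\]
#' @param n_samples sample size N
#' @param order order q of the partial correlation
#' @return list with elements `t` and `p`
#' @export
partial_t_statistic <- function(r_partial, n_samples, order = 1L) {
  df <- n_samples - order - 2
  if (df <= 0)
    stop("need n_samples > order + 2 for the partial correlation test")
  stopifnot(abs(r_partial) <= 1)
  if (abs(r_partial) >= 1)
    return(list(t = sign(r_partial) * Inf, p = 0))
  t <- r_partial * sqrt(df) / sqrt(1 - r_partial^2)
  list(t = t, p = 2 * stats::pt(abs(t), df = df, lower.tail = FALSE))
}
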