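## Representation-quality diagnostics: uniformity, tolerance, and their
## product. Embeddings are L2-normalised onto the unit hypersphere
## before either metric; expectations run over unordered distinct pairs
## (self-pairs excluded, which would bias both metrics optimistically).

#' Uniformity of an embedding
#'
#' Negative logarithm of the average pairwise Gaussian potential of the
#' L2-normalised embeddings,
#' \deqn{-\log \mathrm{mean}_{i<j} \, e^{-t \|z_i - z_j\|_2^2},}
#' negated so that larger values mean a more uniformly spread
#' representation. For unit vectors the value lies in \[0, 4t\]; a
#' collapsed representation scores 0.
#'
#' @param embeddings numeric matrix, one cell per row, no zero rows;
#'   at least 2 rows.
#' @param t Gaussian potential constant (default 2).
#' @return non-negative scalar.
#' @export
uniformityScore <- function(embeddings, t = 2) {
  if (t <= 0) stopf("t must be > 0")
  n <- nrow(embeddings)
  if (is.null(n) || n < 2L) stopf("uniformity needs at least 2 embeddings")
  z <- rowNormalize(embeddings)
  s <- z %*% t(z)
  d2 <- 2 - 2 * s                   # squared distances of unit vectors
  d2[d2 < 0] <- 0
  pot <- exp(-t * d2)
  -log(mean(pot[upper.tri(pot)]))
}

#' Tolerance of a labelled embedding
#'
#' Mean cosine similarity over all unordered pairs of cells sharing a
#' class label; classes with a single member contribute no pairs.
#' Measures how tightly the representation preserves local semantic
#' (same cell-type) structure.
#'
#' @param embeddings numeric matrix, one cell per row, no zero rows.
#' @param labels per-row class labels; at least one class needs two or
#'   more members.
#' @return scalar in \[-1, 1\].
#' @export
toleranceScore <- function(embeddings, labels) {
  labels <- as.character(labels)
  if (nrow(embeddings) != length(labels))
    stopf("one label per embedding row required")
  z <- rowNormalize(embeddings)
  s <- z %*% t(z)
  same <- outer(labels, labels, "==") & upper.tri(s)
  if (!any(same)) stopf("no same-class pair exists")
  mean(s[same])
}

#' Uniformity-tolerance quality product
#'
#' The scalar summary of the uniformity-tolerance trade-off: a good
#' contrastive representation is both globally spread (high uniformity)
#' and locally tight within cell types (high tolerance), so the best
#' method is the one with the highest product.
#'
#' @inheritParams toleranceScore
#' @param t Gaussian potential constant (default 2).
#' @return `list(uniformity, tolerance, product)`.
#' @export
qualityProduct <- function(embeddings, labels, t = 2) {
  u <- uniformityScore(embeddings, t)
  tol <- toleranceScore(embeddings, labels)
  list(uniformity = u, tolerance = tol, product = u * tol)
}
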