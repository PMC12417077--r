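## Contrastive losses over projector outputs.
##
## For an anchor cell i in a batch, H+ holds the projections of the
## in-batch cells sharing i's cell-type label (the anchor itself
## excluded) and H- those with a different label. The restricted
## ("afrcl") loss normalises each positive similarity by itself plus the
## negatives only; the conventional supervised contrastive ("supcon")
## loss normalises by all positives and negatives. Similarities are
## cosine, divided by a temperature tau; all exponentials are evaluated
## with per-anchor max subtraction.

#' Cosine similarity of two vectors
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return their cosine similarity, clamped to \[-1, 1\] against
#'   rounding.
#' @export
cosineSimilarity <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stopf("cosine similarity is undefined for a zero vector")
  min(1, max(-1, sum(a * b) / (na * nb)))
}

# L2-normalise rows; errors on zero rows.
rowNormalize <- function(x) {
  r <- sqrt(rowSums(x * x))
  if (any(r == 0)) stopf("row %d is a zero vector", which(r == 0)[1L])
  x / r
}

#' Positive/negative sets for an anchor
#'
#' @param labels batch label vector.
#' @param anchor index of the anchor cell within the batch.
#' @return `list(positives, negatives)`: in-batch indices sharing / not
#'   sharing the anchor's label, the anchor excluded from both.
#' @export
anchorContext <- function(labels, anchor) {
  labels <- as.character(labels)
  idx <- seq_along(labels)[-anchor]
  list(positives = idx[labels[idx] == labels[anchor]],
       negatives = idx[labels[idx] != labels[anchor]])
}

# Cosine similarities of the anchor to the rest of the batch, over tau.
anchorLogits <- function(projections, anchor, temperature) {
  z <- rowNormalize(projections)
  s <- as.vector(z %*% z[anchor, ])
  pmin(1, pmax(-1, s)) / temperature
}

#' Per-anchor contrastive losses
#'
#' `afclAnchorLoss()` computes, for anchor i with positive set H+ and
#' negative set H-,
#' \deqn{L_i = -\frac{1}{|H^+|} \sum_{q \in H^+} \log
#'   \frac{e^{F(h_i,h_q)/\tau}}
#'        {e^{F(h_i,h_q)/\tau} + \sum_{l \in H^-} e^{F(h_i,h_l)/\tau}}}
#' with F the cosine similarity. `supconAnchorLoss()` replaces the
#' denominator by the sum over all of H+ and H- (the conventional
#' supervised contrastive form). Both are finite, non-negative, and
#' coincide when |H+| = 1.
#'
#' @param projections numeric matrix, one batch cell per row (projector
#'   outputs); no row may be zero.
#' @param labels batch label vector.
#' @param anchor index of the anchor cell; its positive set must be
#'   non-empty.
#' @param temperature tau > 0.
#' @return the anchor loss (a non-negative scalar).
#' @export
afclAnchorLoss <- function(projections, labels, anchor, temperature = 0.1) {
  anchorLossImpl(projections, labels, anchor, temperature, "afrcl")
}

#' @rdname afclAnchorLoss
#' @export
supconAnchorLoss <- function(projections, labels, anchor,
                             temperature = 0.1) {
  anchorLossImpl(projections, labels, anchor, temperature, "supcon")
}

anchorLossImpl <- function(projections, labels, anchor, temperature,
                           variant) {
  if (temperature <= 0) stopf("temperature must be > 0")
  ctx <- anchorContext(labels, anchor)
  if (length(ctx$positives) == 0L)
    stopf("anchor %d has no in-batch positive", anchor)
  a <- anchorLogits(projections, anchor, temperature)
  mx <- max(a[c(ctx$positives, ctx$negatives)])
  e <- exp(a - mx)
  sneg <- sum(e[ctx$negatives])
  denom <- if (variant == "afrcl") e[ctx$positives] + sneg
           else sum(e[c(ctx$positives, ctx$negatives)])
  mean(log(denom) - log(e[ctx$positives]))
}

#' Batch-level contrastive loss
#'
#' Accumulates the anchor losses over every cell of a batch and divides
#' by m, the number of cells. Anchors whose in-batch positive set is
#' empty contribute 0 (they cannot form a pair) but still count in m.
#'
#' @param projections numeric matrix, one batch cell per row.
#' @param labels batch label vector.
#' @param temperature tau > 0.
#' @param variant `"afrcl"` or `"supcon"`.
#' @return `list(value, nAnchors, degenerate)`: the normalised batch
#'   loss, the number of anchors that had a positive, and a flag raised
#'   when no anchor did (all labels distinct; the loss is then 0).
#' @export
batchLoss <- function(projections, labels, temperature = 0.1,
                      variant = c("afrcl", "supcon")) {
  variant <- match.arg(variant)
  m <- nrow(projections)
  if (m < 2L) stopf("a batch needs at least 2 cells")
  total <- 0
  nAnchors <- 0L
  for (i in seq_len(m)) {
    if (sum(labels == labels[i]) < 2L) next
    total <- total + anchorLossImpl(projections, labels, i, temperature,
                                    variant)
    nAnchors <- nAnchors + 1L
  }
  if (nAnchors == 0L)
    warning("no anchor has an in-batch positive; batch loss is 0",
            call. = FALSE)
  list(value = total / m, nAnchors = nAnchors, degenerate = nAnchors == 0L)
}

#' Batch loss and its gradient with respect to the projections
#'
#' Analytic gradient of [batchLoss()] through the cosine similarities
#' and the row normalisation; used by the training loop and verified
#' against finite differences in the test-suite.
#'
#' @inheritParams batchLoss
#' @return `list(value, grad)` with `grad` shaped like `projections`.
#' @export
batchLossGradient <- function(projections, labels, temperature = 0.1,
                              variant = c("afrcl", "supcon")) {
  variant <- match.arg(variant)
  m <- nrow(projections)
  if (m < 2L) stopf("a batch needs at least 2 cells")
  labels <- as.character(labels)
  r <- sqrt(rowSums(projections * projections))
  if (any(r == 0)) stopf("row %d is a zero vector", which(r == 0)[1L])
  z <- projections / r
  s <- z %*% t(z)
  s[s > 1] <- 1; s[s < -1] <- -1
  a <- s / temperature
  G <- matrix(0, m, m)  # G[i, j] = dL/da[i, j], i the anchor
  total <- 0
  for (i in seq_len(m)) {
    ctx <- anchorContext(labels, i)
    P <- ctx$positives; N <- ctx$negatives
    if (length(P) == 0L) next
    mx <- max(a[i, c(P, N)])
    e <- exp(a[i, ] - mx)
    if (variant == "afrcl") {
      sneg <- sum(e[N])
      denom <- e[P] + sneg
      total <- total + mean(log(denom) - log(e[P]))
      G[i, P] <- -(1 / length(P)) * sneg / denom
      if (length(N) > 0L)
        G[i, N] <- e[N] * sum(1 / denom) / length(P)
    } else {
      denom <- sum(e[c(P, N)])
      total <- total + mean(log(denom) - log(e[P]))
      G[i, P] <- e[P] / denom - 1 / length(P)
      G[i, N] <- e[N] / denom
    }
  }
  G <- G / (temperature * m)
  dz <- (G + t(G)) %*% z
  # back through z = h / ||h||: project out the radial component
  dh <- (dz - rowSums(dz * z) * z) / r
  list(value = total / m, grad = dh)
}
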