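# Evaluation battery: partition agreement (ARI, NMI) and local batch/domain
# mixing (LISI).

check_labels <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (length(a) < 2L) stop("need at least two observations")
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, adjusted for chance;
#' permutation-invariant, 1 for identical partitions, around 0 for
#' independent ones (can be negative).
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar ARI.
#' @export
ari <- function(a, b) {
  check_labels(a, b)
  ct <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

entropy_nat <- function(x) {
  p <- as.vector(x) / sum(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information
#'
#' Mutual information between the partitions normalized by the arithmetic
#' mean of their entropies; in `[0, 1]`. Degenerate single-class-vs-
#' single-class input (both entropies zero) is defined as 1, since two
#' all-in-one partitions are identical.
#'
#' @inheritParams ari
#' @return scalar NMI.
#' @export
nmi <- function(a, b) {
  check_labels(a, b)
  ct <- table(a, b)
  ha <- entropy_nat(rowSums(ct))
  hb <- entropy_nat(colSums(ct))
  if (ha == 0 && hb == 0) return(1)
  n <- length(a)
  p <- ct / n
  pa <- rowSums(p); pb <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0)
      mi <- mi + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  }
  unname(mi / ((ha + hb) / 2))
}

#' Local inverse Simpson's index
#'
#' For each observation, Gaussian-kernel weights over its neighbourhood are
#' calibrated by bisection on the bandwidth so their entropy matches the
#' target perplexity; the index is then `1 / sum_k p_k^2` of the weighted
#' label distribution. Values run from 1 (only one label locally) to the
#' number of classes (perfect local mixing). With batch labels, higher means
#' better batch mixing; with domain labels, lower means crisper domains.
#'
#' @param embedding numeric matrix (observations x dimensions).
#' @param labels label vector (batch ids or domain labels).
#' @param perplexity neighbourhood size target (default 30); must be smaller
#'   than the number of observations.
#' @return numeric vector, one value per observation.
#' @export
lisi <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (length(labels) != n) stop("labels must match embedding rows")
  if (perplexity >= n) stop("perplexity must be smaller than n")
  labels <- as.integer(factor(labels))
  q <- max(labels)
  if (q == 1L) return(rep(1, n))
  k_nn <- min(n - 1L, max(15L, ceiling(3 * perplexity)))
  target <- log(perplexity)
  out <- numeric(n)
  block <- 256L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    D2 <- outer(rowSums(embedding[idx, , drop = FALSE]^2),
                rowSums(embedding^2), "+") -
      2 * embedding[idx, , drop = FALSE] %*% t(embedding)
    for (r in seq_along(idx)) {
      i <- idx[r]
      d2 <- D2[r, ]
      d2[i] <- Inf
      o <- order(d2)[seq_len(k_nn)]
      dd <- pmax(d2[o], 0)
      if (max(dd) <= 0) {
        w <- rep(1 / k_nn, k_nn)      # all neighbours coincide: uniform
      } else {
        lo <- 0; hi <- Inf; beta <- 1 / (mean(dd) + 1e-12)
        for (iter in seq_len(60L)) {
          w <- exp(-beta * dd)
          sw <- sum(w)
          if (sw <= 0) { h <- 0 } else {
            w <- w / sw
            h <- -sum(w[w > 0] * log(w[w > 0]))
          }
          if (abs(h - target) < 1e-5) break
          if (h > target) { lo <- beta
            beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
          } else { hi <- beta
            beta <- (beta + lo) / 2
          }
        }
        if (sum(exp(-beta * dd)) <= 0) w <- rep(1 / k_nn, k_nn)
      }
      pk <- vapply(seq_len(q), function(k) sum(w[labels[o] == k]), 0)
      out[i] <- 1 / sum(pk^2)
    }
  }
  out
}

#' Summarize clustering and mixing quality of a fit
#'
#' @param fit an `st_fit`.
#' @param truth_labels reference domain labels aligned with the global spot
#'   index.
#' @param perplexity LISI perplexity.
#' @return one-row tibble with ARI, NMI, and median/mean batch- and
#'   domain-LISI.
#' @export
evaluate_fit <- function(fit, truth_labels = NULL, perplexity = 30) {
  stopifnot(inherits(fit, "st_fit"))
  batch <- as.integer(factor(fit$spots$batch,
                             levels = unique(fit$spots$batch)))
  bl <- lisi(fit$embedding, batch, perplexity)
  dl <- lisi(fit$embedding, fit$domains, perplexity)
  tibble(
    ari = if (is.null(truth_labels)) NA_real_ else ari(fit$domains,
                                                       truth_labels),
    nmi = if (is.null(truth_labels)) NA_real_ else nmi(fit$domains,
                                                       truth_labels),
    batch_lisi_median = median(bl), batch_lisi_mean = mean(bl),
    domain_lisi_median = median(dl), domain_lisi_mean = mean(dl)
  )
}
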