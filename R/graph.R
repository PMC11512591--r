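# Combined spatial neighborhood graph: intra-slice KNN (or radius) edges on
# coordinates, inter-slice MNN edges on expression, merged into one symmetric
# 0/1 adjacency matrix over all spots.

# Platform defaults for intra-slice edges.
intra_default <- function(platform) {
  switch(platform,
         ST = list(method = "knn", K = 4L),
         Visium = list(method = "knn", K = 6L),
         SlideSeqV2 = list(method = "radius", r = 50))
}

# Blockwise k-nearest-neighbour indices of rows of X among rows of Y under
# Euclidean distance. Self-matches are NOT excluded here. Ties are broken by
# lower index in Y. Returns an nrow(X) x k integer matrix.
knn_index <- function(X, Y, k, block = 512L) {
  n <- nrow(X); m <- nrow(Y)
  k <- min(k, m)
  out <- matrix(0L, n, k)
  ynorm <- rowSums(Y^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    D2 <- outer(rowSums(X[idx, , drop = FALSE]^2), ynorm, "+") -
      2 * X[idx, , drop = FALSE] %*% t(Y)
    for (r in seq_along(idx)) {
      o <- order(D2[r, ], seq_len(m))[seq_len(k)]
      out[idx[r], ] <- o
    }
  }
  out
}

canonical_edges <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- lo != hi
  e <- unique(cbind(i = lo[keep], j = hi[keep]))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Intra-slice K-nearest-neighbour edges
#'
#' Directed KNN relation under Euclidean distance, symmetrized by union
#' (an edge is kept if either endpoint selects the other). Self-pairs are
#' excluded; distance ties are broken by lower spot index.
#'
#' @param coords numeric matrix of spot positions (n x 2).
#' @param K neighbours per spot; 6 is the conventional choice for Visium
#'   hexagonal arrays and 4 for cartesian ST arrays.
#' @return integer matrix with columns `i`, `j` (local indices, `i < j`).
#' @export
knn_edges <- function(coords, K) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) {
    warning("fewer than 2 spots: empty edge set")
    return(canonical_edges(integer(0), integer(0)))
  }
  stopifnot(K >= 1L)
  nn <- knn_index(coords, coords, min(K + 1L, n))
  # drop the self column wherever it appears
  ii <- rep(seq_len(n), each = ncol(nn))
  jj <- as.integer(t(nn))
  keep <- ii != jj
  ii <- ii[keep]; jj <- jj[keep]
  # keep only first K neighbours per source spot after self removal
  sel <- unlist(lapply(split(seq_along(ii), ii),
                       function(s) s[seq_len(min(K, length(s)))]),
                use.names = FALSE)
  canonical_edges(ii[sel], jj[sel])
}

#' Intra-slice fixed-radius edges
#'
#' Connects every pair of spots strictly closer than `r` (Euclidean). Used
#' for bead-based platforms (Slide-seqV2, conventional radius 50 in bead
#' units) where local density varies too much for a fixed K.
#'
#' @inheritParams knn_edges
#' @param r radius; strict inequality, so pairs at exactly `r` are excluded.
#' @return integer matrix with columns `i`, `j` (`i < j`).
#' @export
radius_edges <- function(coords, r) {
  stopifnot(r > 0)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) return(canonical_edges(integer(0), integer(0)))
  ii <- integer(0); jj <- integer(0)
  block <- 1024L
  ynorm <- rowSums(coords^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    D2 <- outer(rowSums(coords[idx, , drop = FALSE]^2), ynorm, "+") -
      2 * coords[idx, , drop = FALSE] %*% t(coords)
    w <- which(D2 < r^2 - 1e-12, arr.ind = TRUE)
    ii <- c(ii, idx[w[, 1]]); jj <- c(jj, w[, 2])
  }
  canonical_edges(ii, jj)
}

#' Inter-slice mutual-nearest-neighbour edges
#'
#' A pair (i in slice a, j in slice b) is connected iff j is among the K
#' nearest rows of `expr_b` to row i AND i is among the K nearest rows of
#' `expr_a` to row j, distances Euclidean in the supplied representation
#' (typically a joint principal-component space).
#'
#' @param expr_a,expr_b numeric matrices with a common column space.
#' @param K mutual-neighbour depth (conventional default 2).
#' @return integer matrix with columns `i` (row of a), `j` (row of b).
#' @export
mnn_edges <- function(expr_a, expr_b, K = 2L) {
  expr_a <- as.matrix(expr_a); expr_b <- as.matrix(expr_b)
  if (ncol(expr_a) != ncol(expr_b))
    stop("expression matrices must share the same columns")
  stopifnot(K >= 1L)
  ab <- knn_index(expr_a, expr_b, min(K, nrow(expr_b)))  # for each a: K in b
  ba <- knn_index(expr_b, expr_a, min(K, nrow(expr_a)))  # for each b: K in a
  hits_ab <- cbind(rep(seq_len(nrow(expr_a)), ncol(ab)), as.integer(ab))
  inv <- matrix(FALSE, nrow(expr_a), nrow(expr_b))
  inv[cbind(as.integer(ba), rep(seq_len(nrow(expr_b)), ncol(ba)))] <- TRUE
  keep <- inv[hits_ab]
  e <- unique(hits_ab[keep, , drop = FALSE])
  colnames(e) <- c("i", "j")
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# Joint PCA representation for one slice pair: rows of both slices projected
# on the top principal components of the pair-centered stacked matrix.
pair_pca <- function(Ya, Yb, n_pc = 50L) {
  Z <- rbind(Ya, Yb)
  Z <- sweep(Z, 2, colMeans(Z), "-")
  n_pc <- min(n_pc, ncol(Z), nrow(Z) - 1L)
  sv <- svd(Z, nu = 0, nv = n_pc)
  S <- Z %*% sv$v
  list(a = S[seq_len(nrow(Ya)), , drop = FALSE],
       b = S[nrow(Ya) + seq_len(nrow(Yb)), , drop = FALSE])
}

#' Spot graph constructor
#'
#' @param n total number of spots.
#' @param edges tibble/data.frame with integer columns `i`, `j` (global
#'   indices) and a `kind` column (`"intra"` or `"inter"`).
#' @param batch integer vector of batch membership per spot.
#' @return an object of class `spot_graph` holding the edge table, the
#'   symmetric sparse 0/1 adjacency `A` and per-spot batch indices.
#' @export
spot_graph <- function(n, edges, batch) {
  edges <- as_tibble(edges)
  stopifnot(all(c("i", "j", "kind") %in% names(edges)),
            length(batch) == n)
  if (nrow(edges) > 0) {
    stopifnot(all(edges$i >= 1), all(edges$j <= n), all(edges$i != edges$j))
    A <- sparseMatrix(i = c(edges$i, edges$j), j = c(edges$j, edges$i),
                      x = 1, dims = c(n, n))
    A@x[] <- 1  # de-duplicate any doubled entries back to 0/1
  } else {
    A <- sparseMatrix(i = integer(0), j = integer(0), dims = c(n, n))
  }
  structure(list(n = n, edges = edges, A = A, batch = as.integer(batch)),
            class = "spot_graph")
}

#' @export
print.spot_graph <- function(x, ...) {
  cat(sprintf("<spot_graph> %d spots, %d edges (%d intra, %d inter)\n",
              x$n, nrow(x$edges), sum(x$edges$kind == "intra"),
              sum(x$edges$kind == "inter")))
  invisible(x)
}

#' Build the combined neighborhood graph of a multi-slice dataset
#'
#' Intra-slice edges come from spatial KNN (cartesian/hex arrays) or a fixed
#' radius (bead platforms), chosen per slice from its platform tag unless
#' overridden. Inter-slice edges are expression MNN pairs computed for every
#' slice pair in a joint PCA space of the pair's centered expression.
#'
#' @param dataset an assembled `st_dataset` with normalized expression.
#' @param k_intra optional override of the per-platform intra-slice K.
#' @param radius optional override of the bead-platform radius.
#' @param k_mnn mutual-nearest-neighbour depth across slices (default 2).
#' @param n_pc number of principal components for the MNN representation
#'   (default 50).
#' @param verbose log a per-batch neighbour-count summary?
#' @return a [spot_graph].
#' @export
build_graph <- function(dataset, k_intra = NULL, radius = NULL, k_mnn = 2L,
                        n_pc = 50L, verbose = TRUE) {
  stopifnot(inherits(dataset, "st_dataset"))
  ns <- vapply(dataset$slices, n_spots, 1L)
  offset <- c(0L, cumsum(ns))[seq_along(ns)]
  B <- length(dataset$slices)
  all_edges <- list()
  for (b in seq_len(B)) {
    s <- dataset$slices[[b]]
    cfg <- intra_default(s$platform)
    e <- if (cfg$method == "knn") {
      knn_edges(s$coords, k_intra %||% cfg$K)
    } else {
      radius_edges(s$coords, radius %||% cfg$r)
    }
    if (nrow(e) == 0L)
      warning("slice '", s$batch_id, "' produced no intra-slice edges")
    all_edges[[length(all_edges) + 1L]] <-
      tibble(i = e[, 1] + offset[b], j = e[, 2] + offset[b], kind = "intra")
  }
  if (B > 1L) {
    exprs <- lapply(dataset$slices, function(s) as.matrix(s$expr))
    for (a in seq_len(B - 1L)) for (b in (a + 1L):B) {
      pc <- pair_pca(exprs[[a]], exprs[[b]], n_pc = n_pc)
      e <- mnn_edges(pc$a, pc$b, K = k_mnn)
      if (nrow(e) == 0L)
        warning("no MNN pairs between slices '", names(dataset$slices)[a],
                "' and '", names(dataset$slices)[b], "'")
      if (nrow(e) > 0L)
        all_edges[[length(all_edges) + 1L]] <-
          tibble(i = e[, 1] + offset[a], j = e[, 2] + offset[b],
                 kind = "inter")
    }
  }
  edges <- dplyr::bind_rows(all_edges)
  edges <- dplyr::distinct(tibble(i = pmin(edges$i, edges$j),
                                  j = pmax(edges$i, edges$j),
                                  kind = edges$kind))
  g <- spot_graph(dataset$n_total, edges, batch_index(dataset))
  if (verbose) {
    deg <- Matrix::rowSums(g$A)
    for (b in seq_len(B))
      message(sprintf("graph: slice '%s' mean degree %.2f",
                      names(dataset$slices)[b],
                      mean(deg[batch_index(dataset) == b])))
  }
  g
}

# Neighbor list + per-edge Potts weights (eta_{batch(i)} + eta_{batch(j)}),
# precomputed once for the ICM sweeps and the Potts prior evaluation.
neighbor_lists <- function(graph, eta) {
  eta <- rep_len(eta, max(graph$batch))
  ii <- c(graph$edges$i, graph$edges$j)
  jj <- c(graph$edges$j, graph$edges$i)
  w <- eta[graph$batch[ii]] + eta[graph$batch[jj]]
  ord <- order(ii)
  ii <- ii[ord]; jj <- jj[ord]; w <- w[ord]
  nbr <- vector("list", graph$n)
  wts <- vector("list", graph$n)
  if (length(ii) > 0) {
    splits <- split(seq_along(ii), factor(ii, levels = seq_len(graph$n)))
    for (k in seq_len(graph$n)) {
      s <- splits[[k]]
      nbr[[k]] <- jj[s]
      wts[[k]] <- w[s]
    }
  } else {
    for (k in seq_len(graph$n)) { nbr[[k]] <- integer(0); wts[[k]] <- numeric(0) }
  }
  list(nbr = nbr, wts = wts)
}
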