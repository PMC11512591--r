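# Shared fixtures and independent oracles for the test suite.

# ---- brute-force graph oracles ----------------------------------------

bf_knn_edges <- function(coords, K) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  hits <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    o <- order(D[i, -i], seq_len(n)[-i])
    nb <- (seq_len(n)[-i])[o][seq_len(min(K, n - 1))]
    hits[i, nb] <- TRUE
  }
  sym <- hits | t(hits)
  w <- which(sym & upper.tri(sym), arr.ind = TRUE)
  e <- cbind(i = w[, 1], j = w[, 2])
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

bf_radius_edges <- function(coords, r) {
  D <- as.matrix(dist(coords))
  w <- which(D < r & upper.tri(D), arr.ind = TRUE)
  e <- cbind(i = w[, 1], j = w[, 2])
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

bf_mnn_edges <- function(A, B, K) {
  na <- nrow(A); nb <- nrow(B)
  D <- as.matrix(dist(rbind(A, B)))[seq_len(na), na + seq_len(nb),
                                    drop = FALSE]
  out <- NULL
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    j_in_i <- j %in% order(D[i, ], seq_len(nb))[seq_len(min(K, nb))]
    i_in_j <- i %in% order(D[, j], seq_len(na))[seq_len(min(K, na))]
    if (j_in_i && i_in_j) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) return(cbind(i = integer(0), j = integer(0)))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  colnames(out) <- c("i", "j")
  out
}

# ---- contingency-table oracles ----------------------------------------

bf_ari <- function(a, b) {
  n <- length(a)
  s11 <- s_same_a <- s_same_b <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    s11 <- s11 + (sa && sb)
    s_same_a <- s_same_a + sa
    s_same_b <- s_same_b + sb
  }
  tot <- choose(n, 2)
  exp11 <- s_same_a * s_same_b / tot
  max11 <- (s_same_a + s_same_b) / 2
  if (max11 == exp11) return(1)
  (s11 - exp11) / (max11 - exp11)
}

bf_nmi <- function(a, b) {
  ct <- table(a, b) / length(a)
  pa <- rowSums(ct); pb <- colSums(ct)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  if (H(pa) == 0 && H(pb) == 0) return(1)
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (ct[i, j] > 0) mi <- mi + ct[i, j] * log(ct[i, j] / (pa[i] * pb[j]))
  unname(mi / ((H(pa) + H(pb)) / 2))
}

# ---- small-instance builders ------------------------------------------

# Dataset built directly from expression matrices (already on log scale).
ds_from_mats <- function(mats, platform = "ST") {
  slices <- lapply(seq_along(mats), function(b) {
    Y <- mats[[b]]
    rownames(Y) <- paste0("b", b, "_", seq_len(nrow(Y)))
    colnames(Y) <- paste0("g", seq_len(ncol(Y)))
    co <- cbind(x = seq_len(nrow(Y)), y = rep(0, nrow(Y)))
    rownames(co) <- rownames(Y)
    slice_data(coords = co, platform = platform,
               batch_id = paste0("s", b), expr = Y)
  })
  assemble_dataset(slices)
}

edgeless_graph <- function(n, batch) {
  spot_graph(n, tibble::tibble(i = integer(0), j = integer(0),
                               kind = character(0)), batch)
}

# A random consistent (dataset, graph, params, state, hyper) tuple for
# update-rule oracle tests.
random_instance <- function(seed, n = 6L, p = 4L, d = 2L, q = 2L, B = 1L) {
  set.seed(seed)
  mats <- lapply(seq_len(B), function(b) matrix(rnorm(n * p), n, p))
  ds <- ds_from_mats(mats)
  ds <- center_genes(ds)
  ntot <- n * B
  hyper <- st_hyper(q = q, d = d, eta = 0.5, nu_omega = 2)
  edges <- tibble::tibble(i = 1L, j = 2L, kind = "intra")
  graph <- spot_graph(ntot, edges, rep(seq_len(B), each = n))
  params <- st_params(
    L = matrix(rnorm(p * d, 0, 0.5), p, d),
    gamma = matrix(rnorm(p * B, 0, 0.1), p, B),
    Tt = matrix(exp(rnorm(p * B, 0.5, 0.2)), p, B),
    mu = matrix(rnorm(d * q), d, q),
    Lambda = {
      A <- matrix(rnorm(d * d, 0, 0.3), d, d)
      diag(d) + crossprod(A)
    }
  )
  state <- st_state(f = matrix(rnorm(ntot * d), ntot, d),
                    omega = exp(rnorm(ntot, 0, 0.3)),
                    c = rep_len(seq_len(q), ntot))
  list(ds = ds, graph = graph, params = params, state = state,
       hyper = hyper)
}

# ---- independent hard-EM oracle in the projected space ----------------
# Used by the reduction test: B = 1, eta = 0, T = I, gamma = 0, loadings
# fixed at an orthonormal L0. Everything runs in d dimensions.
oracle_hard_em <- function(Y, L0, q, nu, seed, max_iter,
                           Sigma_mu = diag(100, ncol(L0)),
                           n_Lambda = ncol(L0),
                           Sigma_Lambda = diag(100, ncol(L0))) {
  d <- ncol(L0)
  Fp <- Y %*% L0                       # projected data (T = I, L0'L0 = I)
  set.seed(seed)
  Fw <- apply(Fp, 2, function(z) {
    qq <- quantile(z, c(0.02, 0.98)); pmin(pmax(z, qq[1]), qq[2])
  })
  km <- kmeans(Fw, centers = q, nstart = 10L, iter.max = 100L)
  cl <- km$cluster
  mu <- sapply(seq_len(q), function(k) colMeans(Fp[cl == k, , drop = FALSE]))
  muw <- sapply(seq_len(q), function(k) colMeans(Fw[cl == k, , drop = FALSE]))
  W <- crossprod(Fw - t(muw)[cl, , drop = FALSE]) / nrow(Fp)
  Lambda <- solve(W + diag(1e-6, d))
  omega <- rep(1, nrow(Fp))
  f <- Fp
  SmuInv <- solve(Sigma_mu)
  for (it in seq_len(max_iter)) {
    # factor update: (omega Lambda + I) f = Fp + omega Lambda mu_c
    for (i in seq_len(nrow(Fp))) {
      A <- omega[i] * Lambda + diag(d)
      f[i, ] <- solve(A, Fp[i, ] + omega[i] * (Lambda %*% mu[, cl[i]]))
    }
    D <- f - t(mu)[cl, , drop = FALSE]
    delta2 <- rowSums((D %*% Lambda) * D)
    omega <- (nu + d) / (nu + delta2)
    # labels: eta = 0 -> per-spot argmin Mahalanobis (ties to smaller k)
    d2 <- sapply(seq_len(q), function(k) {
      Dk <- sweep(f, 2, mu[, k]); rowSums((Dk %*% Lambda) * Dk)
    })
    cl <- apply(-0.5 * omega * d2, 1, which.max)
    # cluster updates
    for (k in seq_len(q)) {
      idx <- which(cl == k)
      if (length(idx) == 0) next
      om <- omega[idx]
      mu[, k] <- solve(SmuInv + sum(om) * Lambda,
                       Lambda %*% colSums(f[idx, , drop = FALSE] * om))
    }
    D <- f - t(mu)[cl, , drop = FALSE]
    S <- crossprod(D * sqrt(omega))
    Lambda <- max(n_Lambda + nrow(Fp) - d - 1, 1e-8) *
      solve(solve(Sigma_Lambda) + S)
    Lambda <- (Lambda + t(Lambda)) / 2
  }
  list(labels = cl, f = f, mu = mu, Lambda = Lambda)
}

# ---- cached recovery fixture ------------------------------------------

.fixture_env <- new.env(parent = emptyenv())

recovery_fixture <- function(data_seed, max_iter = 60L) {
  key <- paste0("rec", data_seed)
  if (!exists(key, envir = .fixture_env)) {
    sim <- simulate_dataset(sim_config(), seed = data_seed)
    ds <- center_genes(sim$dataset)
    graph <- build_graph(ds, verbose = FALSE)
    hyper <- st_hyper(q = 5, d = 10, eta = 1.5)
    fit <- suppressMessages(
      fit_em(ds, graph, hyper, seed = 1L, max_iter = max_iter))
    assign(key, list(sim = sim, ds = ds, graph = graph, fit = fit),
           envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

subspace_angle_deg <- function(L1, L2) {
  Q1 <- svd(L1)$u
  Q2 <- svd(L2)$u
  max(acos(pmin(1, svd(crossprod(Q1, Q2))$d)) * 180 / pi)
}
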