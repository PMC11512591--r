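# EM/ICM inference.
#
# Point-value (hard) EM: factor scores, per-spot precisions and labels are
# updated to their conditional posterior mean (omega) or mode (f, c), and
# each parameter block is updated to the maximizer of its slice of the
# complete-data log posterior. The tracked objective is the
# omega-marginalized log joint, which every step provably does not decrease.

.ctx <- function(dataset) {
  bidx <- batch_index(dataset)
  list(Y = expr_matrix(dataset),
       rows = split(seq_len(dataset$n_total), bidx),
       bidx = bidx,
       B = length(dataset$slices),
       p = length(dataset$genes))
}

# ---- E-steps -----------------------------------------------------------

.factors_update <- function(ctx, params, state, hyper) {
  L <- params$L
  d <- ncol(L)
  U <- chol_safe(params$Lambda)                 # Lambda = U'U
  P <- backsolve(U, diag(d))                    # U^{-1}
  Lmu <- t(params$Lambda %*% params$mu)         # q x d
  Fnew <- state$f
  for (b in seq_len(ctx$B)) {
    rows <- ctx$rows[[b]]
    tb <- params$Tt[, b]
    Lt <- L * tb
    M <- crossprod(L, Lt)                       # L' T_b L
    eg <- eigen((t(P) %*% M %*% P + t(t(P) %*% M %*% P)) / 2,
                symmetric = TRUE)
    PV <- P %*% eg$vectors                      # (omega Lambda + M)^{-1} =
    ev <- pmax(eg$values, 0)                    #   PV diag(1/(omega+ev)) PV'
    R <- sweep(ctx$Y[rows, , drop = FALSE], 2, params$gamma[, b], "-")
    G <- R %*% Lt +
      state$omega[rows] * Lmu[state$c[rows], , drop = FALSE]
    W <- G %*% PV
    W <- W / (matrix(state$omega[rows], length(rows), d) +
                matrix(ev, length(rows), d, byrow = TRUE))
    Fnew[rows, ] <- W %*% t(PV)
  }
  Fnew
}

#' Conditional update of the factor scores
#'
#' For each spot solves `(omega Lambda + L' T_b L) f = L' T_b (y - gamma_b) +
#' omega Lambda mu_k`, the posterior mean (and mode) of `f` given the spot's
#' label and precision.
#'
#' @param dataset centered `st_dataset`.
#' @param params [st_params].
#' @param state [st_state] with current labels and omega.
#' @param hyper [st_hyper].
#' @return n x d matrix of updated factor scores.
#' @export
e_step_factors <- function(dataset, params, state, hyper) {
  .factors_update(.ctx(dataset), params, state, hyper)
}

#' Conditional update of the per-spot precisions
#'
#' Posterior mean of the Gamma full conditional:
#' `omega = (nu_omega + d) / (nu_omega + delta2)` with
#' `delta2 = (f - mu_k)' Lambda (f - mu_k)`.
#'
#' @inheritParams e_step_factors
#' @return length-n positive vector.
#' @export
e_step_omega <- function(params, state, hyper) {
  D <- state$f - t(params$mu)[state$c, , drop = FALSE]
  delta2 <- rowSums((D %*% params$Lambda) * D)
  if (any(delta2 < -1e-8)) stop("negative Mahalanobis distance: Lambda broken")
  (hyper$nu_omega + hyper$d) / (hyper$nu_omega + pmax(delta2, 0))
}

.icm_update <- function(nl, params, state, hyper, n_sweeps = 1L) {
  q <- hyper$q
  delta2 <- mahalanobis_sq(state$f, params$mu, params$Lambda)  # n x q
  score0 <- -0.5 * state$omega * delta2          # recycles omega down columns
  lab <- state$c
  n <- length(lab)
  for (sweep_ in seq_len(n_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      sc <- score0[i, ]
      nb <- nl$nbr[[i]]
      if (length(nb) > 0) {
        w <- nl$wts[[i]]
        labs <- lab[nb]
        for (t in seq_along(nb)) sc[labs[t]] <- sc[labs[t]] + w[t]
      }
      new <- which.max(sc)                       # ties -> smallest k
      if (new != lab[i]) { lab[i] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

#' ICM label update
#'
#' Iterated conditional modes on the Potts-regularized label posterior:
#' spots are swept in global-index order and each label is set to
#' `argmax_k [log N_d(f_i; mu_k, omega_i^{-1} Lambda^{-1}) + sum_{j~i, c_j=k}
#' (eta_{b(i)} + eta_{b(j)})]`; ties go to the smaller k. Stops early when a
#' sweep changes nothing.
#'
#' @param graph [spot_graph].
#' @inheritParams e_step_factors
#' @param n_sweeps maximum number of full sweeps.
#' @return integer label vector.
#' @export
e_step_labels_icm <- function(graph, params, state, hyper, n_sweeps = 1L) {
  nl <- neighbor_lists(graph, hyper$eta)
  .icm_update(nl, params, state, hyper, n_sweeps)
}

# ---- M-steps -----------------------------------------------------------

.batch_update <- function(ctx, params, state, hyper) {
  gamma <- params$gamma
  Tt <- params$Tt
  for (b in seq_len(ctx$B)) {
    rows <- ctx$rows[[b]]
    nb <- length(rows)
    if (nb == 0L) { warning("batch ", b, " has no spots; skipped"); next }
    R <- ctx$Y[rows, , drop = FALSE] -
      state$f[rows, , drop = FALSE] %*% t(params$L)
    tb <- Tt[, b]
    gamma[, b] <- tb * colSums(R) / (1 + nb * tb)
    ssr <- colSums(sweep(R, 2, gamma[, b], "-")^2)
    Tt[, b] <- pmax((hyper$nu_t + nb - 2) / (hyper$nu_t + ssr), 1e-6)
  }
  list(gamma = gamma, Tt = Tt)
}

#' M-step for the additive and multiplicative batch effects
#'
#' Given residuals `r = y - L f`, sets `gamma_bj` to the posterior mode under
#' the standard-normal prior, `t_bj gamma-sum / (1 + n_b t_bj)`, then updates
#' each noise precision to the mode of its Gamma full conditional
#' `(nu_t + n_b - 2) / (nu_t + SSR_bj)`, floored at `1e-6`.
#'
#' @inheritParams e_step_factors
#' @return list with elements `gamma` (p x B) and `Tt` (p x B).
#' @export
m_step_batch <- function(dataset, params, state, hyper) {
  .batch_update(.ctx(dataset), params, state, hyper)
}

# Stationary points of the coordinate objective -a l^2/2 + b l + penalty.
.spike_root <- function(a, b, lambda0) b / (a + 1 / lambda0)

.slab_root <- function(a, b, lambda1) {
  A <- a + 1 / lambda1
  ifelse(b == 0, sqrt(2 / A),
         (b + sign(b) * sqrt(b^2 + 8 * A)) / (2 * A))
}

.loadings_update <- function(ctx, params, state, hyper, n_passes = 1L) {
  L <- params$L
  p <- nrow(L); d <- ncol(L)
  l0 <- hyper$lambda0; l1 <- hyper$lambda1
  S <- vector("list", ctx$B); C <- vector("list", ctx$B)
  for (b in seq_len(ctx$B)) {
    Fb <- state$f[ctx$rows[[b]], , drop = FALSE]
    S[[b]] <- crossprod(Fb)
    R0 <- sweep(ctx$Y[ctx$rows[[b]], , drop = FALSE], 2,
                params$gamma[, b], "-")
    C[[b]] <- crossprod(R0, Fb)                  # p x d
  }
  A <- matrix(0, p, d)
  for (b in seq_len(ctx$B)) A <- A + outer(params$Tt[, b], diag(S[[b]]))
  incl <- params$incl
  resp <- matrix(0, p, d)
  p_slab <- params$p_slab
  for (pass in seq_len(n_passes)) for (k in seq_len(d)) {
    a <- A[, k]
    if (any(a <= 0)) {
      g <- which(a <= 0)[1]
      stop("non-positive quadratic coefficient for gene index ", g,
           " (factor ", k, "); factor column has zero weighted energy")
    }
    bvec <- numeric(p)
    for (b in seq_len(ctx$B)) {
      u <- C[[b]][, k] - L %*% S[[b]][, k] + L[, k] * S[[b]][k, k]
      bvec <- bvec + params$Tt[, b] * as.vector(u)
    }
    pk <- p_slab[k]
    cand <- cbind(L[, k],
                  .spike_root(a, bvec, l0),
                  .slab_root(a, bvec, l1))
    val <- -0.5 * a * cand^2 + bvec * cand +
      matrix(loading_prior_logpdf(as.vector(cand), pk, l0, l1), p, 3)
    pick <- max.col(val, ties.method = "first")
    lnew <- cand[cbind(seq_len(p), pick)]
    L[, k] <- lnew
    # marginalized component evidences -> posterior inclusion probability
    v0 <- a + 1 / l0
    v1 <- a + 1 / l1
    le0 <- -0.5 * log(l0 * v0) + bvec^2 / (2 * v0)
    le1 <- log((bvec^2 / v1^2 + 1 / v1) / l1) - 0.5 * log(l1 * v1) +
      bvec^2 / (2 * v1)
    incl[, k] <- if (pk == 0) 0 else if (pk == 1) 1 else
      1 / (1 + exp(log((1 - pk) / pk) + le0 - le1))
    # point responsibilities at the accepted solution (for the p_j update)
    ls0 <- dnorm(lnew, 0, sqrt(l0), log = TRUE)
    ls1 <- pmom_slab_logpdf(lnew, l1)
    resp[, k] <- if (pk == 0) 0 else if (pk == 1) 1 else
      1 / (1 + exp(log((1 - pk) / pk) + ls0 - ls1))
  }
  p_slab <- clip((hyper$alpha_p - 1 + colSums(resp)) /
                   (hyper$alpha_p + hyper$beta_p - 2 + p), 0, 1)
  list(L = L, incl = incl, p_slab = p_slab)
}

#' M-step for the sparse loading matrix
#'
#' Coordinate ascent over loading entries under the spike-and-slab pMOM
#' prior. For entry (j, k) with quadratic statistics `a` (curvature) and `b`
#' (linear term) from the Gaussian likelihood, the spike stationary point is
#' `b / (a + 1/lambda0)` and the slab stationary point solves
#' `l^2 (a + 1/lambda1) - b l - 2 = 0`, i.e.
#' `l = (b + sign(b) sqrt(b^2 + 8 (a + 1/lambda1))) / (2 (a + 1/lambda1))`
#' (`|l| = sqrt(2/(a + 1/lambda1))` at `b = 0`; the pMOM slab repels zero).
#' Among the current value and the two stationary points the update keeps the
#' one with the highest penalized objective, so the step never decreases it.
#' Inclusion probabilities come from the marginalized component evidences,
#' and slab probabilities from the Beta-posterior formula
#' `(alpha_p - 1 + sum_j r_jk) / (alpha_p + beta_p - 2 + p)`.
#'
#' @inheritParams e_step_factors
#' @param n_passes coordinate passes over the d columns (default 1).
#' @return list with `L` (p x d), `incl` (p x d) and `p_slab` (length d).
#' @export
m_step_loadings <- function(dataset, params, state, hyper, n_passes = 1L) {
  .loadings_update(.ctx(dataset), params, state, hyper, n_passes)
}

# Ridge recentering (parameter-expanded EM move). The likelihood is exactly
# invariant under f_i -> f_i + delta_b (i in batch b), gamma_b -> gamma_b -
# L delta_b, so EM contracts this direction extremely slowly; here delta_b is
# set to the exact maximizer of the remaining terms (factor prior + gamma
# prior), a closed-form quadratic, which keeps every monotonicity guarantee.
.recenter_update <- function(ctx, params, state, hyper) {
  L <- params$L
  LtL <- crossprod(L)
  Lam <- params$Lambda
  mu_c <- t(params$mu)[state$c, , drop = FALSE]
  for (b in seq_len(ctx$B)) {
    rows <- ctx$rows[[b]]
    om <- state$omega[rows]
    sw <- sum(om)
    A <- sw * Lam + LtL
    rhs <- -Lam %*% colSums((state$f[rows, , drop = FALSE] -
                               mu_c[rows, , drop = FALSE]) * om) +
      crossprod(L, params$gamma[, b])
    delta <- solve(A, rhs)
    state$f[rows, ] <- sweep(state$f[rows, , drop = FALSE], 2,
                             as.vector(delta), "+")
    params$gamma[, b] <- params$gamma[, b] - as.vector(L %*% delta)
  }
  list(f = state$f, gamma = params$gamma)
}

.clusters_update <- function(params, state, hyper, quiet = FALSE) {
  d <- hyper$d; q <- hyper$q
  mu <- params$mu
  Lam <- params$Lambda
  SmuInv <- solve(hyper$Sigma_mu)
  empty <- integer(0)
  for (k in seq_len(q)) {
    idx <- which(state$c == k)
    if (length(idx) == 0L) { empty <- c(empty, k); next }
    om <- state$omega[idx]
    sw <- sum(om)
    rhs <- SmuInv %*% hyper$mu_mu +
      Lam %*% colSums(state$f[idx, , drop = FALSE] * om)
    mu[, k] <- solve(SmuInv + sw * Lam, rhs)
  }
  if (length(empty) > 0L && !quiet)
    message("m_step_clusters: empty cluster(s) ",
            paste(empty, collapse = ", "), " retained")
  D <- state$f - t(mu)[state$c, , drop = FALSE]
  Sct <- crossprod(D * sqrt(state$omega))
  n <- nrow(state$f)
  df_post <- hyper$n_Lambda + n
  scale_inv <- solve(hyper$Sigma_Lambda) + Sct
  Lambda <- max(df_post - d - 1, 1e-8) * solve(scale_inv)
  Lambda <- (Lambda + t(Lambda)) / 2
  chol_safe(Lambda)
  list(mu = mu, Lambda = Lambda)
}

#' M-step for the cluster means and shared precision
#'
#' `mu_k` is the Gaussian posterior mean given the omega-weighted members of
#' cluster k; `Lambda` is the mode of its Wishart full conditional computed
#' from the omega-weighted scatter of `f - mu_{c}` and the prior
#' `(n_Lambda, Sigma_Lambda)`. Empty clusters keep their previous mean
#' (flagged with a message).
#'
#' @inheritParams e_step_factors
#' @return list with `mu` (d x q) and `Lambda` (d x d).
#' @export
m_step_clusters <- function(params, state, hyper) {
  .clusters_update(params, state, hyper)
}

# ---- initialization ----------------------------------------------------

#' Deterministic initialization of parameters and latent state
#'
#' PCA (SVD of the pooled centered expression) for the loadings and scores,
#' k-means with the given seed for the labels, per-batch residual moments for
#' the batch effects, empirical cluster moments for `mu` and `Lambda`,
#' omega = 1, inclusion probabilities 0.5.
#'
#' @param dataset centered `st_dataset`.
#' @param graph [spot_graph] (unused by the initializer itself; accepted for
#'   interface symmetry).
#' @param hyper [st_hyper].
#' @param seed integer seed controlling k-means.
#' @param fix_loadings optional p x d matrix: use these loadings instead of
#'   the principal axes (they are then also kept fixed by [fit_em()]).
#' @param fix_batch logical: force `gamma = 0`, `T = I` (no batch layer).
#' @return list with elements `params` and `state`.
#' @export
init_state <- function(dataset, graph = NULL, hyper, seed = 1L,
                       fix_loadings = NULL, fix_batch = FALSE) {
  ctx <- .ctx(dataset)
  Y <- ctx$Y
  n <- nrow(Y); p <- ncol(Y)
  d <- hyper$d; q <- hyper$q
  if (q > n) stop("more clusters than spots")
  if (d >= p) stop("latent dimension must be smaller than the gene panel")
  set.seed(seed)
  if (is.null(fix_loadings)) {
    # unit-variance factor convention: scores have unit scale, loadings
    # carry the magnitudes, so the spike/slab prior sees L on its own scale
    sv <- svd(Y, nu = 0, nv = d)
    dvals <- pmax(sv$d[seq_len(d)], 1e-12 * max(sv$d[1], 1))
    L <- sv$v %*% diag(dvals / sqrt(n), d)
    F <- Y %*% sv$v %*% diag(sqrt(n) / dvals, d)
  } else {
    L <- fix_loadings
    stopifnot(nrow(L) == p, ncol(L) == d)
    F <- Y %*% L %*% solve(crossprod(L))
  }
  # k-means labels are computed on winsorized scores: the factor layer is
  # heavy-tailed (Student-t), and raw k-means wastes clusters on outliers
  Fw <- apply(F, 2, function(z) {
    qq <- quantile(z, c(0.02, 0.98))
    pmin(pmax(z, qq[1]), qq[2])
  })
  km <- kmeans(Fw, centers = q, nstart = 10L, iter.max = 100L)
  cl <- km$cluster
  gamma <- matrix(0, p, ctx$B)
  Tt <- matrix(1, p, ctx$B)
  for (b in seq_len(ctx$B)) {
    R <- Y[ctx$rows[[b]], , drop = FALSE] -
      F[ctx$rows[[b]], , drop = FALSE] %*% t(L)
    if (!fix_batch) {
      gamma[, b] <- colMeans(R)
      v <- colMeans(sweep(R, 2, gamma[, b], "-")^2)
      Tt[, b] <- clip(1 / pmax(v, 1e-12), 1e-4, 1e4)
    }
  }
  mu <- matrix(0, d, q)
  for (k in seq_len(q)) {
    idx <- which(cl == k)
    if (length(idx) > 0) mu[, k] <- colMeans(F[idx, , drop = FALSE])
  }
  # Shared precision from the winsorized scores: the raw within-cluster
  # scatter of heavy-tailed factors is outlier-dominated and would start
  # Lambda near a spurious low-precision fixed point of the EM map.
  muw <- matrix(0, d, q)
  for (k in seq_len(q)) {
    idx <- which(cl == k)
    if (length(idx) > 0) muw[, k] <- colMeans(Fw[idx, , drop = FALSE])
  }
  W <- crossprod(Fw - t(muw)[cl, , drop = FALSE]) / n
  Lambda <- solve(W + diag(1e-6, d))
  Lambda <- (Lambda + t(Lambda)) / 2
  params <- st_params(L = L, gamma = gamma, Tt = Tt, mu = mu,
                      Lambda = Lambda)
  state <- st_state(f = F, omega = rep(1, n), c = cl)
  list(params = params, state = state)
}

# ---- main loop ---------------------------------------------------------

#' Fit the model by EM with ICM label updates
#'
#' Iterates factor, precision and label E-steps with the loading, batch and
#' cluster M-steps, tracking the omega-marginalized log joint. Stops when the
#' relative objective change drops below `tol` or after `max_iter`
#' iterations.
#'
#' @param dataset an assembled `st_dataset`; centered automatically if not
#'   already.
#' @param graph optional [spot_graph]; built from the dataset with the
#'   hyperparameter graph settings when `NULL`.
#' @param hyper [st_hyper] (must carry the number of domains `q`).
#' @param max_iter maximum EM iterations (default 30).
#' @param tol relative objective-change tolerance (default `1e-5`).
#' @param icm_sweeps ICM sweeps per label update (default 3).
#' @param seed integer seed for the initialization.
#' @param fix_loadings optional fixed p x d loading matrix (no loading
#'   M-step).
#' @param fix_batch logical; `TRUE` freezes `gamma = 0`, `T = I`.
#' @param verbose print per-iteration objectives?
#' @return an object of class `st_fit` with fields `params`, `latent`,
#'   `objective_trace`, `converged`, `n_iter`, `domains`, `embedding`, plus
#'   the spot table for tidying.
#' @export
fit_em <- function(dataset, graph = NULL, hyper, max_iter = 30L, tol = 1e-5,
                   icm_sweeps = 3L, seed = 1L, fix_loadings = NULL,
                   fix_batch = FALSE, verbose = FALSE) {
  stopifnot(inherits(hyper, "st_hyper"))
  if (!isTRUE(dataset$centered)) {
    msg_log("fit_em: centering genes", verbose = verbose)
    dataset <- center_genes(dataset)
  }
  if (is.null(graph))
    graph <- build_graph(dataset, k_intra = hyper$k_intra,
                         radius = hyper$radius, k_mnn = hyper$k_mnn,
                         verbose = verbose)
  ctx <- .ctx(dataset)
  ini <- init_state(dataset, graph, hyper, seed = seed,
                    fix_loadings = fix_loadings, fix_batch = fix_batch)
  params <- ini$params; state <- ini$state
  nl <- neighbor_lists(graph, hyper$eta)
  obj_prev <- log_joint_marginal(dataset, graph, params, state, hyper)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    state$f <- .factors_update(ctx, params, state, hyper)
    state$omega <- e_step_omega(params, state, hyper)
    state$c <- .icm_update(nl, params, state, hyper, n_sweeps = icm_sweeps)
    if (is.null(fix_loadings)) {
      up <- .loadings_update(ctx, params, state, hyper)
      params$L <- up$L; params$incl <- up$incl; params$p_slab <- up$p_slab
    }
    if (!fix_batch) {
      up <- .batch_update(ctx, params, state, hyper)
      params$gamma <- up$gamma; params$Tt <- up$Tt
      up <- .recenter_update(ctx, params, state, hyper)
      state$f <- up$f; params$gamma <- up$gamma
    }
    up <- .clusters_update(params, state, hyper, quiet = !verbose)
    params$mu <- up$mu; params$Lambda <- up$Lambda
    obj <- log_joint_marginal(dataset, graph, params, state, hyper)
    if (!is.finite(obj))
      stop("objective became non-finite at iteration ", it)
    trace <- c(trace, obj)
    if (verbose) message(sprintf("iter %3d  objective %.4f", it, obj))
    if (abs(obj - obj_prev) < tol * abs(obj_prev)) {
      converged <- TRUE
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  spots <- dataset$spots
  spots$domain <- state$c
  structure(
    list(params = params, latent = state,
         objective_trace = trace, converged = converged,
         n_iter = length(trace), domains = state$c, embedding = state$f,
         hyper = hyper, seed = seed, spots = spots,
         genes = dataset$genes, center = dataset$center,
         graph_summary = c(n = graph$n, edges = nrow(graph$edges))),
    class = "st_fit"
  )
}

#' @export
print.st_fit <- function(x, ...) {
  cat(sprintf(paste0("<st_fit> %d spots, d = %d, q = %d; %d iterations",
                     " (%sconverged)\n  final objective %.2f\n"),
              nrow(x$embedding), x$hyper$d, x$hyper$q, x$n_iter,
              if (x$converged) "" else "not ",
              x$objective_trace[x$n_iter]))
  invisible(x)
}

#' Batch-free reconstruction of expression
#'
#' Returns `x_hat = f L'`, the model's batch-corrected expression on the
#' centered scale; adding `gamma_b` to a batch's rows reproduces the fitted
#' batch-specific mean.
#'
#' @param x an `st_fit`, or an [st_params] when `state` is given.
#' @param state an [st_state] (only when `x` is a parameter bundle).
#' @return n x p numeric matrix.
#' @export
corrected_expression <- function(x, state = NULL) {
  if (inherits(x, "st_fit")) {
    state <- x$latent
    params <- x$params
  } else {
    params <- x
    stopifnot(!is.null(state))
  }
  out <- state$f %*% t(params$L)
  if (inherits(x, "st_fit") && !is.null(x$genes)) colnames(out) <- x$genes
  out
}
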