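# Model and prior layer.
#
# Observation layer:  y_bi = L f_bi + gamma_b + eps_bi,  eps ~ N_p(0, T_b^{-1})
# Factor layer:       f_bi | c_bi = k, omega_bi ~ N_d(mu_k, omega^{-1} Lambda^{-1})
#                     omega_bi ~ Gamma(nu_omega/2, nu_omega/2)
#                     (marginally f is multivariate Student-t with nu_omega df)
# Label layer:        Potts prior on the combined spot graph, strength eta_b.
# Priors:             gamma ~ N(0, I); t_bj ~ Gamma(nu_t/2, nu_t/2);
#                     mu_k ~ N(mu_mu, Sigma_mu); Lambda ~ Wishart(n_Lambda,
#                     Sigma_Lambda); L entries spike-and-slab with a pMOM slab;
#                     slab probabilities p_j ~ Beta(alpha_p, beta_p).

#' Model hyperparameters
#'
#' Collects every fixed quantity of the model with the conventional defaults:
#' spike/slab variances `lambda0 = 0.015` / `lambda1 = 0.871`, Student-t
#' degrees of freedom `nu_omega = 2`, noise-precision prior df `nu_t = 1`,
#' flat Beta(1,1) on slab probabilities, diffuse `Sigma_mu = 100 I` on cluster
#' means and a least-informative Wishart (`n_Lambda = d`, `Sigma_Lambda =
#' 100 I`) on the shared precision.
#'
#' @param q number of spatial domains (required).
#' @param d latent dimension (default 15).
#' @param eta Potts smoothness, recycled per batch (default 1).
#' @param lambda0,lambda1 spike and slab variances of the loading prior.
#' @param nu_omega,nu_t Gamma prior shapes/rates (`nu/2`, `nu/2`).
#' @param mu_mu,Sigma_mu cluster-mean prior (defaults `0`, `100 I`).
#' @param n_Lambda,Sigma_Lambda Wishart prior on the shared precision
#'   (defaults `d`, `100 I`).
#' @param alpha_p,beta_p Beta prior on slab probabilities (defaults 1, 1).
#' @param k_intra,k_mnn,radius graph construction defaults (per-platform K
#'   when `k_intra` is `NULL`).
#' @return a validated object of class `st_hyper`.
#' @export
st_hyper <- function(q, d = 15L, eta = 1,
                     lambda0 = 0.015, lambda1 = 0.871,
                     nu_omega = 2, nu_t = 1,
                     mu_mu = NULL, Sigma_mu = NULL,
                     n_Lambda = NULL, Sigma_Lambda = NULL,
                     alpha_p = 1, beta_p = 1,
                     k_intra = NULL, k_mnn = 2L, radius = 50) {
  d <- as.integer(d); q <- as.integer(q)
  stopifnot(q >= 1L, d >= 1L, all(eta >= 0),
            lambda0 > 0, lambda1 > 0, nu_omega > 0, nu_t > 0,
            alpha_p > 0, beta_p > 0)
  mu_mu <- mu_mu %||% rep(0, d)
  Sigma_mu <- Sigma_mu %||% diag(100, d)
  n_Lambda <- n_Lambda %||% d
  Sigma_Lambda <- Sigma_Lambda %||% diag(100, d)
  stopifnot(length(mu_mu) == d, all(dim(Sigma_mu) == d),
            all(dim(Sigma_Lambda) == d), n_Lambda > d - 1)
  chol_safe(Sigma_mu); chol_safe(Sigma_Lambda)  # SPD checks
  structure(list(d = d, q = q, eta = eta, lambda0 = lambda0,
                 lambda1 = lambda1, nu_omega = nu_omega, nu_t = nu_t,
                 mu_mu = mu_mu, Sigma_mu = Sigma_mu, n_Lambda = n_Lambda,
                 Sigma_Lambda = Sigma_Lambda, alpha_p = alpha_p,
                 beta_p = beta_p, k_intra = k_intra, k_mnn = k_mnn,
                 radius = radius),
            class = "st_hyper")
}

#' Model parameter bundle
#'
#' @param L p x d loading matrix.
#' @param gamma p x B additive batch effects.
#' @param Tt p x B positive noise precisions (diagonal of each batch's
#'   precision matrix).
#' @param mu d x q cluster means.
#' @param Lambda d x d SPD shared precision of the factor layer.
#' @param incl p x d posterior slab-inclusion probabilities.
#' @param p_slab length-d slab probabilities per factor.
#' @return object of class `st_params`.
#' @export
st_params <- function(L, gamma, Tt, mu, Lambda, incl = NULL, p_slab = NULL) {
  d <- ncol(L)
  incl <- incl %||% matrix(0.5, nrow(L), d)
  p_slab <- p_slab %||% rep(0.5, d)
  stopifnot(all(Tt > 0), nrow(mu) == d, all(dim(Lambda) == d),
            all(incl >= 0 & incl <= 1), all(p_slab >= 0 & p_slab <= 1),
            nrow(gamma) == nrow(L))
  chol_safe(Lambda)
  structure(list(L = L, gamma = gamma, Tt = Tt, mu = mu, Lambda = Lambda,
                 incl = incl, p_slab = p_slab),
            class = "st_params")
}

#' Latent state bundle
#'
#' @param f n x d factor scores.
#' @param omega length-n positive per-spot precisions.
#' @param c length-n integer domain labels in `1..q`.
#' @return object of class `st_state`.
#' @export
st_state <- function(f, omega, c) {
  stopifnot(nrow(f) == length(omega), length(c) == length(omega),
            all(omega > 0))
  structure(list(f = f, omega = omega, c = as.integer(c)),
            class = "st_state")
}

#' Unnormalized Potts log prior
#'
#' Evaluates `sum_b sum_i eta_b sum_{j~i} 1(c_i = c_j)` over the graph: the
#' sum runs over ordered incidences, so each unordered edge contributes once
#' from each endpoint (with that endpoint's batch smoothness), i.e. a
#' concordant intra-batch edge adds `2 eta_b` and a concordant inter-batch
#' edge adds `eta_a + eta_b`. The intractable normalizing constant is never
#' computed; `eta` is fixed, so the unnormalized form suffices for inference.
#'
#' @param c integer labels in `1..q`.
#' @param graph a [spot_graph].
#' @param eta per-batch smoothness (recycled), all `>= 0`.
#' @param q number of label states (for validation; default `max(c)`).
#' @return scalar log-prior value (up to the normalizing constant).
#' @export
potts_log_prior_unnorm <- function(c, graph, eta, q = max(c)) {
  stopifnot(length(c) == graph$n, all(eta >= 0))
  if (any(c < 1L | c > q)) stop("labels must lie in 1..q")
  if (nrow(graph$edges) == 0L) return(0)
  eta <- rep_len(eta, max(graph$batch))
  i <- graph$edges$i; j <- graph$edges$j
  w <- eta[graph$batch[i]] + eta[graph$batch[j]]
  sum(w * (c[i] == c[j]))
}

#' Log density of the pMOM slab
#'
#' The nonlocal product-moment density `(l^2 / lambda1) N(l; 0, lambda1)`,
#' which vanishes at zero (so selected loadings are repelled from 0) and
#' integrates to one.
#'
#' @param l evaluation point(s).
#' @param lambda1 slab variance (> 0).
#' @return log density, `-Inf` at `l = 0`.
#' @export
pmom_slab_logpdf <- function(l, lambda1) {
  stopifnot(lambda1 > 0)
  out <- ifelse(l == 0, -Inf,
                log(l^2 / lambda1) + dnorm(l, 0, sqrt(lambda1), log = TRUE))
  out
}

#' Log density of the spike-and-slab loading prior
#'
#' Mixture `(1 - pi) N(l; 0, lambda0) + pi pMOM(l; lambda1)` with mixing
#' probability `pi = incl_prob`.
#'
#' @inheritParams pmom_slab_logpdf
#' @param incl_prob slab probability in `[0, 1]` (vectorized).
#' @param lambda0 spike variance.
#' @return log density (vectorized over `l` / `incl_prob`).
#' @export
loading_prior_logpdf <- function(l, incl_prob, lambda0, lambda1) {
  stopifnot(all(incl_prob >= 0 & incl_prob <= 1), lambda0 > 0)
  spike <- dnorm(l, 0, sqrt(lambda0), log = TRUE)
  slab <- pmom_slab_logpdf(l, lambda1)
  n <- max(length(l), length(incl_prob))
  pi_ <- rep_len(incl_prob, n)
  spike <- rep_len(spike, n); slab <- rep_len(slab, n)
  out <- numeric(n)
  z <- pi_ == 0; o <- pi_ == 1; mid <- !z & !o
  out[z] <- spike[z]
  out[o] <- slab[o]
  out[mid] <- log_sum_exp(log(1 - pi_[mid]) + spike[mid],
                          log(pi_[mid]) + slab[mid])
  out
}

# Shared pieces of the two joint-density flavours: everything except the
# factor/omega layer.
log_joint_common <- function(dataset, graph, params, state, hyper) {
  Y <- expr_matrix(dataset)
  bidx <- batch_index(dataset)
  B <- length(dataset$slices)
  p <- ncol(Y)
  obs <- 0
  for (b in seq_len(B)) {
    rows <- which(bidx == b)
    R <- Y[rows, , drop = FALSE] -
      state$f[rows, , drop = FALSE] %*% t(params$L)
    R <- sweep(R, 2, params$gamma[, b], "-")
    tb <- params$Tt[, b]
    obs <- obs + 0.5 * length(rows) * (sum(log(tb)) - p * log(2 * pi)) -
      0.5 * sum(colSums(R^2) * tb)
  }
  potts <- potts_log_prior_unnorm(state$c, graph, hyper$eta, q = hyper$q)
  pri <- sum(dnorm(params$gamma, 0, 1, log = TRUE)) +
    sum(dgamma(params$Tt, shape = hyper$nu_t / 2, rate = hyper$nu_t / 2,
               log = TRUE)) +
    sum(vapply(seq_len(hyper$q), function(k)
      dmvnorm_log(params$mu[, k], hyper$mu_mu, hyper$Sigma_mu), 0)) +
    dwishart_log(params$Lambda, hyper$n_Lambda, hyper$Sigma_Lambda) +
    sum(loading_prior_logpdf(as.vector(params$L),
                             rep(params$p_slab, each = p),
                             hyper$lambda0, hyper$lambda1)) +
    sum(dbeta(params$p_slab, hyper$alpha_p, hyper$beta_p, log = TRUE))
  list(obs = obs, potts = potts, priors = pri)
}

#' Complete-data log posterior (up to the Potts constant)
#'
#' Point evaluation of the full joint: Gaussian observation term, Gaussian
#' factor term at the given `omega`, Gamma terms for `omega`, the
#' unnormalized Potts prior, and all parameter priors. This is the objective
#' each E/M update is verified against.
#'
#' @param dataset centered `st_dataset`.
#' @param graph [spot_graph] over all spots.
#' @param params [st_params].
#' @param state [st_state].
#' @param hyper [st_hyper].
#' @return scalar log density (finite for valid input).
#' @export
log_joint <- function(dataset, graph, params, state, hyper) {
  parts <- log_joint_common(dataset, graph, params, state, hyper)
  d <- hyper$d
  delta2 <- rowSums(((state$f - t(params$mu)[state$c, , drop = FALSE]) %*%
                       params$Lambda) *
                      (state$f - t(params$mu)[state$c, , drop = FALSE]))
  ldet <- logdet_spd(params$Lambda)
  fac <- sum(0.5 * d * log(state$omega) + 0.5 * ldet -
               0.5 * d * log(2 * pi) - 0.5 * state$omega * delta2)
  om <- sum(dgamma(state$omega, shape = hyper$nu_omega / 2,
                   rate = hyper$nu_omega / 2, log = TRUE))
  total <- parts$obs + fac + om + parts$potts + parts$priors
  if (!is.finite(total)) {
    comp <- c(observation = parts$obs, factors = fac, omega = om,
              potts = parts$potts, priors = parts$priors)
    stop("non-finite log_joint component: ",
         paste(names(comp)[!is.finite(comp)], collapse = ", "))
  }
  total
}

#' Log posterior with the per-spot precisions integrated out
#'
#' Identical to [log_joint()] except that the factor layer is evaluated under
#' the marginal multivariate Student-t density (omega integrated against its
#' Gamma prior). Because every EM update either maximizes the
#' omega-expected complete-data objective or leaves it unchanged, this
#' marginal objective is non-decreasing along the fit and is the quantity
#' tracked in the objective trace.
#'
#' @inheritParams log_joint
#' @return scalar log density.
#' @export
log_joint_marginal <- function(dataset, graph, params, state, hyper) {
  parts <- log_joint_common(dataset, graph, params, state, hyper)
  d <- hyper$d; nu <- hyper$nu_omega
  D <- state$f - t(params$mu)[state$c, , drop = FALSE]
  delta2 <- rowSums((D %*% params$Lambda) * D)
  ldet <- logdet_spd(params$Lambda)
  fac <- sum(lgamma((nu + d) / 2) - lgamma(nu / 2) - 0.5 * d * log(nu * pi) +
               0.5 * ldet - 0.5 * (nu + d) * log1p(delta2 / nu))
  total <- parts$obs + fac + parts$potts + parts$priors
  if (!is.finite(total)) stop("non-finite marginal log joint")
  total
}
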