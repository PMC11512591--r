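# Priors, Potts energy and the joint density.

test_that("pMOM slab density integrates to 1, vanishes at 0, is symmetric", {
  l1 <- 0.871
  int <- integrate(function(l) exp(pmom_slab_logpdf(l, l1)), -Inf, Inf,
                   rel.tol = 1e-10)
  expect_equal(int$value, 1, tolerance = 1e-6)
  expect_identical(pmom_slab_logpdf(0, l1), -Inf)
  xs <- c(0.1, 0.7, 2.3)
  expect_equal(pmom_slab_logpdf(xs, l1), pmom_slab_logpdf(-xs, l1))
  # second moment of the kernel is 3 * lambda1
  m2 <- integrate(function(l) l^2 * exp(pmom_slab_logpdf(l, l1)),
                  -Inf, Inf, rel.tol = 1e-10)
  expect_equal(m2$value, 3 * l1, tolerance = 1e-5)
})

test_that("spike-and-slab mixture collapses correctly at the ends", {
  l0 <- 0.015; l1 <- 0.871
  xs <- seq(-2, 2, by = 0.23)
  expect_equal(loading_prior_logpdf(xs, 0, l0, l1),
               dnorm(xs, 0, sqrt(l0), log = TRUE))
  expect_identical(loading_prior_logpdf(0, 1, l0, l1), -Inf)
  # pi = 0.5 at l = 0.3 equals the direct two-component sum
  hand <- log(0.5 * dnorm(0.3, 0, sqrt(l0)) +
                0.5 * (0.3^2 / l1) * dnorm(0.3, 0, sqrt(l1)))
  expect_equal(loading_prior_logpdf(0.3, 0.5, l0, l1), hand,
               tolerance = 1e-12)
})

test_that("Potts energy follows the double-sum convention", {
  g <- spot_graph(2, tibble::tibble(i = 1L, j = 2L, kind = "intra"),
                  batch = c(1L, 1L))
  expect_equal(potts_log_prior_unnorm(c(1L, 1L), g, eta = 1), 2)
  expect_equal(potts_log_prior_unnorm(c(1L, 2L), g, eta = 1), 0)
  expect_equal(potts_log_prior_unnorm(c(1L, 2L), g, eta = 0), 0)
  expect_error(potts_log_prior_unnorm(c(1L, 5L), g, eta = 1, q = 2),
               "1..q")
  # all-equal labels on a random graph: eta * 2|E| (single batch)
  set.seed(2)
  n <- 12
  co <- matrix(runif(2 * n), n, 2)
  e <- knn_edges(co, 2)
  g2 <- spot_graph(n, tibble::tibble(i = e[, 1], j = e[, 2],
                                     kind = "intra"), rep(1L, n))
  expect_equal(potts_log_prior_unnorm(rep(1L, n), g2, eta = 0.7),
               0.7 * 2 * nrow(e))
  # inter-batch edge: one eta from each endpoint's batch
  g3 <- spot_graph(2, tibble::tibble(i = 1L, j = 2L, kind = "inter"),
                   batch = c(1L, 2L))
  expect_equal(potts_log_prior_unnorm(c(2L, 2L), g3, eta = c(1, 3)), 4)
})

test_that("log_joint matches a term-by-term hand computation (single spot, d = 1, p = 1)", {
  # careful hand evaluation of every term of the joint
  y <- 0.7; f <- 0.4; omega <- 1.3; gam <- 0.1; tt <- 2; L <- 0.5
  mu <- 0.2; Lam <- 1.5; pslab <- 0.5
  ds <- ds_from_mats(list(matrix(y, 1, 1)))
  ds$centered <- TRUE  # use the raw value; no centering shift
  hyper <- st_hyper(q = 1, d = 1, eta = 1, nu_omega = 2, nu_t = 1,
                    Sigma_mu = matrix(100, 1, 1), n_Lambda = 1,
                    Sigma_Lambda = matrix(100, 1, 1))
  g <- edgeless_graph(1, 1L)
  params <- st_params(L = matrix(L, 1, 1), gamma = matrix(gam, 1, 1),
                      Tt = matrix(tt, 1, 1), mu = matrix(mu, 1, 1),
                      Lambda = matrix(Lam, 1, 1),
                      p_slab = pslab)
  state <- st_state(f = matrix(f, 1, 1), omega = omega, c = 1L)
  hand <- dnorm(y, L * f + gam, 1 / sqrt(tt), log = TRUE) +
    dnorm(f, mu, 1 / sqrt(omega * Lam), log = TRUE) +
    dgamma(omega, 1, rate = 1, log = TRUE) +
    0 +                                              # no edges
    dnorm(gam, 0, 1, log = TRUE) +
    dgamma(tt, 0.5, rate = 0.5, log = TRUE) +
    dnorm(mu, 0, 10, log = TRUE) +
    # Wishart_1(df = 1, scale = 100) at Lam
    (-0.5 * log(Lam) - Lam / 200 - 0.5 * log(2) - 0.5 * log(100) -
       lgamma(0.5)) +
    log(0.5 * dnorm(L, 0, sqrt(0.015)) +
          0.5 * (L^2 / 0.871) * dnorm(L, 0, sqrt(0.871))) +
    dbeta(pslab, 1, 1, log = TRUE)
  expect_equal(log_joint(ds, g, params, state, hyper), hand,
               tolerance = 1e-8)
})

test_that("log_joint is linear in eta and invariant to spot reordering", {
  inst <- random_instance(31, n = 8, p = 5, d = 2, q = 2)
  hy0 <- inst$hyper; hy0$eta <- 0
  hy1 <- inst$hyper; hy1$eta <- 1
  base0 <- log_joint(inst$ds, inst$graph, inst$params, inst$state, hy0)
  base1 <- log_joint(inst$ds, inst$graph, inst$params, inst$state,
                     inst$hyper)
  base2 <- log_joint(inst$ds, inst$graph, inst$params, inst$state, hy1)
  conc <- potts_log_prior_unnorm(inst$state$c, inst$graph, 1)
  expect_equal(base1 - base0, 0.5 * conc, tolerance = 1e-10)
  expect_equal(base2 - base0, conc, tolerance = 1e-10)

  # permutation of the global spot order leaves the value unchanged
  set.seed(1)
  perm <- sample(8)
  Y <- expr_matrix(inst$ds)
  ds2 <- ds_from_mats(list(Y[perm, , drop = FALSE]))
  ds2$centered <- TRUE
  inst$ds$centered <- TRUE
  e <- inst$graph$edges
  inv <- order(perm)
  g2 <- spot_graph(8, tibble::tibble(i = pmin(inv[e$i], inv[e$j]),
                                     j = pmax(inv[e$i], inv[e$j]),
                                     kind = e$kind), rep(1L, 8))
  st2 <- st_state(f = inst$state$f[perm, , drop = FALSE],
                  omega = inst$state$omega[perm], c = inst$state$c[perm])
  expect_equal(log_joint(ds2, g2, inst$params, st2, inst$hyper),
               log_joint(inst$ds, inst$graph, inst$params, inst$state,
                         inst$hyper),
               tolerance = 1e-9)
})

test_that("factor scale mixture has the Student-t marginal (F-distributed Mahalanobis)", {
  # omega ~ Gamma(nu/2, nu/2), f | omega ~ N(mu, (omega Lambda)^-1)
  # => (f - mu)' Lambda (f - mu) / d ~ F(d, nu)
  sim <- simulate_dataset(sim_config(B = 2, width = 100, height = 100,
                                     p = 12, d = 10, q = 2, eta = 0,
                                     potts_sweeps = 1),
                          seed = 77)
  tr <- sim$truth
  D <- tr$f - t(tr$mu)[tr$labels, , drop = FALSE]
  stat <- rowSums((D %*% tr$Lambda) * D) / ncol(tr$f)
  ks <- suppressWarnings(ks.test(stat, pf, df1 = 10, df2 = 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("hyperparameter defaults carry the standard prior settings", {
  h <- st_hyper(q = 3, d = 4)
  expect_equal(h$lambda0, 0.015)
  expect_equal(h$lambda1, 0.871)
  expect_equal(h$nu_omega, 2)
  expect_equal(h$nu_t, 1)
  expect_equal(h$alpha_p, 1); expect_equal(h$beta_p, 1)
  expect_equal(h$Sigma_mu, diag(100, 4))
  expect_equal(h$n_Lambda, 4)
  expect_equal(h$Sigma_Lambda, diag(100, 4))
  expect_equal(h$mu_mu, rep(0, 4))
  expect_error(st_hyper(q = 3, d = 4, n_Lambda = 2), "n_Lambda")
})
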