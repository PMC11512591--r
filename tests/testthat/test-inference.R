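# EM update rules against numeric-optimization/quadrature oracles, ICM
# against exhaustive search, and the fitting loop's contracts.

test_that("factor update maximizes the joint over each spot's score", {
  inst <- random_instance(101, n = 3, p = 3, d = 2, q = 2)
  inst$ds$centered <- TRUE
  Fhat <- e_step_factors(inst$ds, inst$params, inst$state, inst$hyper)
  for (i in 1:3) {
    obj <- function(v) {
      st <- inst$state; st$f[i, ] <- v
      -log_joint(inst$ds, inst$graph, inst$params, st, inst$hyper)
    }
    opt <- optim(inst$state$f[i, ], obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    expect_equal(Fhat[i, ], opt$par, tolerance = 1e-4)
  }
  # prior collapse: L = 0 makes the posterior mean the cluster mean
  p0 <- inst$params; p0$L[] <- 0
  F0 <- e_step_factors(inst$ds, p0, inst$state, inst$hyper)
  expect_equal(F0, t(p0$mu)[inst$state$c, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("omega update is the Gamma posterior mean", {
  inst <- random_instance(55, n = 5, p = 4, d = 3, q = 2)
  om <- e_step_omega(inst$params, inst$state, inst$hyper)
  nu <- inst$hyper$nu_omega; d <- inst$hyper$d
  for (i in 1:5) {
    Dv <- inst$state$f[i, ] - inst$params$mu[, inst$state$c[i]]
    delta2 <- drop(t(Dv) %*% inst$params$Lambda %*% Dv)
    # quadrature of omega against its full conditional
    dens <- function(w) w^((nu + d) / 2 - 1) * exp(-w * (nu + delta2) / 2)
    num <- integrate(function(w) w * dens(w), 0, Inf, rel.tol = 1e-10)$value
    den <- integrate(dens, 0, Inf, rel.tol = 1e-10)$value
    expect_equal(om[i], num / den, tolerance = 1e-6)
  }
  # delta2 = 0 with nu = 2, d = 10 gives exactly (2 + 10) / 2 = 6
  hy <- st_hyper(q = 1, d = 10, nu_omega = 2)
  st <- st_state(f = matrix(0, 1, 10), omega = 1, c = 1L)
  pp <- st_params(L = matrix(0, 11, 10), gamma = matrix(0, 11, 1),
                  Tt = matrix(1, 11, 1), mu = matrix(0, 10, 1),
                  Lambda = diag(10))
  expect_equal(e_step_omega(pp, st, hy), 6)
})

test_that("ICM labels match exhaustive search on a 4-spot path", {
  set.seed(8)
  d <- 2; q <- 2; n <- 4
  hyper <- st_hyper(q = q, d = d, eta = 0.8)
  edges <- tibble::tibble(i = 1:3, j = 2:4, kind = "intra")
  g <- spot_graph(n, edges, rep(1L, n))
  params <- st_params(L = matrix(0, 3, d), gamma = matrix(0, 3, 1),
                      Tt = matrix(1, 3, 1),
                      mu = cbind(c(-1.5, 0), c(1.5, 0)),
                      Lambda = diag(2))
  f <- rbind(c(-1.6, 0.1), c(-1.2, 0), c(1.4, 0.2), c(1.3, -0.1))
  state <- st_state(f = f, omega = rep(1, n), c = rep(1L, n))
  icm <- e_step_labels_icm(g, params, state, hyper, n_sweeps = 10)
  # exhaustive maximization of the label posterior
  score <- function(lab) {
    s <- 0
    for (i in 1:n) {
      Dv <- f[i, ] - params$mu[, lab[i]]
      s <- s - 0.5 * state$omega[i] * drop(t(Dv) %*% params$Lambda %*% Dv)
    }
    s + potts_log_prior_unnorm(lab, g, hyper$eta, q = q)
  }
  grid <- as.matrix(expand.grid(1:2, 1:2, 1:2, 1:2))
  best <- grid[which.max(apply(grid, 1, score)), ]
  expect_equal(icm, unname(as.integer(best)))
  # eta = 0 reduces to the independent density argmax per spot
  hy0 <- hyper; hy0$eta <- 0
  ind <- e_step_labels_icm(g, params, state, hy0, n_sweeps = 1)
  d2 <- sapply(1:q, function(k) {
    Dk <- sweep(f, 2, params$mu[, k]); rowSums((Dk %*% params$Lambda) * Dk)
  })
  expect_equal(ind, unname(apply(d2, 1, which.min)))
  # very large eta on a connected graph with near-identical scores
  hyB <- hyper; hyB$eta <- 50
  one <- e_step_labels_icm(g, params,
                           st_state(f = f * 0, omega = rep(1, n),
                                    c = c(1L, 1L, 1L, 2L)),
                           hyB, n_sweeps = 10)
  expect_equal(length(unique(one)), 1L)
})

test_that("batch M-step maximizes the gamma and precision slices", {
  inst <- random_instance(7, n = 8, p = 3, d = 2, q = 2)
  inst$ds$centered <- TRUE
  up <- m_step_batch(inst$ds, inst$params, inst$state, inst$hyper)
  # gamma slice, holding T at its pre-update value
  for (j in 1:3) {
    obj_g <- function(v) {
      pp <- inst$params; pp$gamma[j, 1] <- v
      -log_joint(inst$ds, inst$graph, pp, inst$state, inst$hyper)
    }
    o <- optimize(obj_g, c(-5, 5), tol = 1e-10)
    expect_equal(up$gamma[j, 1], o$minimum, tolerance = 1e-4)
  }
  # precision slice, holding gamma at its post-update value
  pp_g <- inst$params; pp_g$gamma <- up$gamma
  for (j in 1:3) {
    obj_t <- function(v) {
      pp <- pp_g; pp$Tt[j, 1] <- v
      -log_joint(inst$ds, inst$graph, pp, inst$state, inst$hyper)
    }
    o <- optimize(obj_t, c(1e-4, 50), tol = 1e-10)
    expect_equal(up$Tt[j, 1], o$minimum, tolerance = 1e-4)
  }
  # zero residuals give zero additive effects
  st0 <- inst$state
  ds0 <- inst$ds
  Y0 <- st0$f %*% t(inst$params$L)
  ds0$slices[[1]]$expr <- Y0
  colnames(ds0$slices[[1]]$expr) <- ds0$genes
  up0 <- m_step_batch(ds0, inst$params, st0, inst$hyper)
  expect_equal(up0$gamma, matrix(0, 3, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("loading coordinate roots maximize their penalized objectives", {
  set.seed(19)
  for (rep in 1:10) {
    a <- runif(1, 0.5, 30)
    b <- rnorm(1, 0, 3)
    l1 <- 0.871; l0 <- 0.015
    slab <- spotweave:::.slab_root(a, b, l1)
    obj_s <- function(l) -(-0.5 * a * l^2 + b * l + pmom_slab_logpdf(l, l1))
    lim <- if (slab > 0) c(1e-8, 10) else c(-10, -1e-8)
    o <- optimize(obj_s, lim, tol = 1e-12)
    expect_equal(slab, o$minimum, tolerance = 1e-4)
    spike <- spotweave:::.spike_root(a, b, l0)
    obj_p <- function(l) -(-0.5 * a * l^2 + b * l +
                             dnorm(l, 0, sqrt(l0), log = TRUE))
    o2 <- optimize(obj_p, c(-10, 10), tol = 1e-12)
    expect_equal(spike, o2$minimum, tolerance = 1e-4)
  }
  # b = 0: the pMOM slab repels zero, |l| = sqrt(2 / (a + 1/lambda1))
  a <- 4
  expect_equal(abs(spotweave:::.slab_root(a, 0, 0.871)),
               sqrt(2 / (a + 1 / 0.871)), tolerance = 1e-12)
})

test_that("loading M-step never decreases its slice of the joint", {
  inst <- random_instance(23, n = 10, p = 6, d = 3, q = 2)
  inst$ds$centered <- TRUE
  before <- log_joint(inst$ds, inst$graph, inst$params, inst$state,
                      inst$hyper)
  up <- m_step_loadings(inst$ds, inst$params, inst$state, inst$hyper)
  pp <- inst$params; pp$L <- up$L
  after <- log_joint(inst$ds, inst$graph, pp, inst$state, inst$hyper)
  expect_gte(after, before - 1e-10)
  expect_true(all(up$incl >= 0 & up$incl <= 1))
  expect_true(all(up$p_slab >= 0 & up$p_slab <= 1))
})

test_that("cluster M-step maximizes the mu and Lambda slices", {
  inst <- random_instance(3, n = 10, p = 4, d = 2, q = 2)
  up <- m_step_clusters(inst$params, inst$state, inst$hyper)
  inst$ds$centered <- TRUE
  for (k in 1:2) {
    obj_m <- function(v) {
      pp <- inst$params; pp$mu[, k] <- v
      -log_joint(inst$ds, inst$graph, pp, inst$state, inst$hyper)
    }
    o <- optim(inst$params$mu[, k], obj_m, method = "BFGS",
               control = list(reltol = 1e-14))
    expect_equal(up$mu[, k], o$par, tolerance = 1e-4)
  }
  # Lambda slice via its Cholesky parameterization, mu at post-update value
  pp_m <- inst$params; pp_m$mu <- up$mu
  obj_L <- function(th) {
    U <- matrix(0, 2, 2); U[1, 1] <- exp(th[1]); U[2, 2] <- exp(th[2])
    U[1, 2] <- th[3]
    pp <- pp_m; pp$Lambda <- crossprod(U)
    -log_joint(inst$ds, inst$graph, pp, inst$state, inst$hyper)
  }
  U0 <- chol(up$Lambda)
  o <- optim(c(log(U0[1, 1]), log(U0[2, 2]), U0[1, 2]), obj_L,
             method = "BFGS", control = list(reltol = 1e-14, maxit = 1000))
  Uo <- matrix(0, 2, 2); Uo[1, 1] <- exp(o$par[1]); Uo[2, 2] <- exp(o$par[2])
  Uo[1, 2] <- o$par[3]
  expect_equal(up$Lambda, crossprod(Uo), tolerance = 1e-4)
  # flat-prior limit with unit omega: mu_k is the plain cluster mean
  hyF <- st_hyper(q = 2, d = 2, Sigma_mu = diag(1e8, 2))
  stF <- inst$state; stF$omega <- rep(1, length(stF$omega))
  upF <- m_step_clusters(inst$params, stF, hyF)
  for (k in 1:2)
    expect_equal(upF$mu[, k],
                 colMeans(stF$f[stF$c == k, , drop = FALSE]),
                 tolerance = 1e-5)
})

test_that("initialization is deterministic and recovers noiseless low-rank data", {
  sim <- simulate_dataset(sim_config(width = 8, height = 8, p = 30, d = 4,
                                     q = 3, noise_level = 0, gamma_sd = 0,
                                     B = 1, potts_sweeps = 5), seed = 5)
  ds <- center_genes(sim$dataset)
  hy <- st_hyper(q = 3, d = 4)
  i1 <- init_state(ds, hyper = hy, seed = 42)
  i2 <- init_state(ds, hyper = hy, seed = 42)
  expect_identical(i1, i2)
  expect_equal(i1$state$omega, rep(1, ds$n_total))
  # zero-noise rank-d data is reconstructed exactly by the PCA init
  Y <- expr_matrix(ds)
  expect_lt(max(abs(Y - i1$state$f %*% t(i1$params$L))), 1e-8)
  expect_error(init_state(ds, hyper = st_hyper(q = ds$n_total + 1, d = 4),
                          seed = 1), "more clusters")
})

test_that("fit_em runs one iteration at tol = Inf and is seed-deterministic", {
  sim <- simulate_dataset(sim_config(width = 8, height = 8, p = 25, d = 3,
                                     q = 3, potts_sweeps = 5), seed = 6)
  ds <- center_genes(sim$dataset)
  g <- build_graph(ds, verbose = FALSE)
  hy <- st_hyper(q = 3, d = 3, eta = 1)
  f1 <- suppressMessages(fit_em(ds, g, hy, max_iter = 10, tol = Inf,
                                seed = 4))
  expect_equal(f1$n_iter, 1L)
  expect_equal(length(f1$objective_trace), 1L)
  f2 <- suppressMessages(fit_em(ds, g, hy, max_iter = 4, seed = 9))
  f3 <- suppressMessages(fit_em(ds, g, hy, max_iter = 4, seed = 9))
  expect_identical(f2$params, f3$params)
  expect_identical(f2$domains, f3$domains)
  expect_identical(f2$objective_trace, f3$objective_trace)
  expect_identical(f2$domains, f2$latent$c)
})

test_that("corrected expression is the rank-d batch-free reconstruction", {
  inst <- random_instance(12, n = 6, p = 5, d = 2, q = 2)
  xhat <- corrected_expression(inst$params, inst$state)
  expect_equal(xhat, inst$state$f %*% t(inst$params$L))
  expect_lte(qr(xhat)$rank, 2)
  st0 <- inst$state; st0$f[] <- 0
  expect_equal(corrected_expression(inst$params, st0),
               matrix(0, 6, 5), ignore_attr = TRUE)
})

test_that("corrected expression tracks the truth on near-noiseless data", {
  sim <- simulate_dataset(sim_config(width = 10, height = 10, p = 40, d = 3,
                                     q = 3, noise_level = 0.02,
                                     potts_sweeps = 10), seed = 13)
  ds <- center_genes(sim$dataset)
  g <- build_graph(ds, verbose = FALSE)
  fit <- suppressMessages(fit_em(ds, g, st_hyper(q = 3, d = 3, eta = 1.5),
                                 seed = 1, max_iter = 30))
  xh <- corrected_expression(fit)
  xt <- sweep(sim$truth$x, 2, colMeans(sim$truth$x))
  cors <- vapply(seq_len(nrow(xh)),
                 function(i) cor(xh[i, ], xt[i, ]), 0)
  expect_gte(median(cors), 0.99)
})

test_that("raising eta never lowers neighbour concordance of the output labels", {
  for (s in 1:5) {
    sim <- simulate_dataset(sim_config(width = 10, height = 10, p = 30,
                                       d = 3, q = 3, potts_sweeps = 10),
                            seed = 100 + s)
    ds <- center_genes(sim$dataset)
    g <- build_graph(ds, verbose = FALSE)
    conc <- function(fit) {
      e <- g$edges[g$edges$kind == "intra", ]
      mean(fit$domains[e$i] == fit$domains[e$j])
    }
    f0 <- suppressMessages(fit_em(ds, g, st_hyper(q = 3, d = 3, eta = 0),
                                  seed = 1, max_iter = 15))
    f2 <- suppressMessages(fit_em(ds, g, st_hyper(q = 3, d = 3, eta = 2),
                                  seed = 1, max_iter = 15))
    expect_gte(conc(f2), conc(f0))
  }
})
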