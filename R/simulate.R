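# Generative simulator: Potts labels on a lattice -> Student-t factor scores
# -> sparse pMOM loadings -> additive/multiplicative batch effects -> noise.
# Emits continuous (already normalized-scale) expression plus full ground
# truth, so recovery of every parameter block can be scored.

#' Gibbs-sample Potts labels on a rectangular 4-neighbour lattice
#'
#' Sequential-scan Gibbs sampler targeting the Potts distribution with the
#' double-sum convention (each concordant lattice edge contributes `2 eta`),
#' started from independent uniform labels.
#'
#' @param width,height lattice dimensions.
#' @param q number of states.
#' @param eta smoothness (`0` gives i.i.d. uniform labels).
#' @param n_sweeps full Gibbs sweeps (default 100).
#' @param seed integer seed.
#' @return `height x width` integer matrix of labels in `1..q`.
#' @export
sample_potts <- function(width, height, q, eta, n_sweeps = 100L, seed = 1L) {
  stopifnot(width >= 1L, height >= 1L, q >= 1L, eta >= 0, n_sweeps >= 1L)
  set.seed(seed)
  n <- width * height
  lab <- sample.int(q, n, replace = TRUE)
  if (q == 1L) return(matrix(lab, height, width))
  idx <- matrix(seq_len(n), height, width)
  nbr <- vector("list", n)
  for (r in seq_len(height)) for (co in seq_len(width)) {
    nb <- integer(0)
    if (r > 1L) nb <- c(nb, idx[r - 1L, co])
    if (r < height) nb <- c(nb, idx[r + 1L, co])
    if (co > 1L) nb <- c(nb, idx[r, co - 1L])
    if (co < width) nb <- c(nb, idx[r, co + 1L])
    nbr[[idx[r, co]]] <- nb
  }
  if (eta == 0) {
    # conditionals are uniform: the start is already an exact draw
    return(matrix(lab, height, width))
  }
  for (s in seq_len(n_sweeps)) {
    for (i in seq_len(n)) {
      cnt <- tabulate(lab[nbr[[i]]], nbins = q)
      w <- exp(2 * eta * cnt)
      lab[i] <- sample.int(q, 1L, prob = w)
    }
  }
  matrix(lab, height, width)
}

#' Per-batch presets for the additive/multiplicative effect magnitudes
#'
#' `gamma_sd` is the per-gene standard deviation of the additive shift;
#' `batch_scales` multiply the per-gene noise precisions, so unequal values
#' give batches with genuinely different noise floors.
#'
#' @param level `"small"`, `"moderate"` or `"large"`.
#' @return list with `gamma_sd` and `batch_scales`.
#' @export
batch_preset <- function(level = c("moderate", "small", "large")) {
  switch(match.arg(level),
         small = list(gamma_sd = 0.3, batch_scales = c(4, 5)),
         moderate = list(gamma_sd = 1.0, batch_scales = c(3, 6)),
         large = list(gamma_sd = 2.0, batch_scales = c(2, 8)))
}

#' Simulation configuration with the default recovery scenario
#'
#' Defaults describe the reference study: two 40 x 40 lattice slices
#' (B = 2, n_b = 1600), p = 200 genes, d = 10 latent factors, q = 5 domains,
#' Potts smoothness 1.5, Student-t degrees of freedom 2 and moderate batch
#' effects.
#'
#' @param B number of slices.
#' @param width,height lattice size per slice.
#' @param p,d,q genes, latent dimension, domains.
#' @param eta Potts smoothness used to draw the labels.
#' @param batch_effects preset name passed to [batch_preset()], or `NULL` to
#'   use `gamma_sd` / `batch_scales` directly.
#' @param gamma_sd additive-effect standard deviation per gene.
#' @param batch_scales per-batch noise-precision scales (recycled).
#' @param noise_level noise standard-deviation multiplier (0 = noiseless).
#' @param nu_omega Student-t degrees of freedom of the factor layer.
#' @param sparsity fraction of loading entries that are non-zero (slab).
#' @param mu_sd standard deviation of the cluster-mean draw.
#' @param potts_sweeps Gibbs sweeps for the label draw.
#' @return named list of settings.
#' @export
sim_config <- function(B = 2L, width = 40L, height = 40L, p = 200L, d = 10L,
                       q = 5L, eta = 1.5, batch_effects = "moderate",
                       gamma_sd = NULL, batch_scales = NULL, noise_level = 1,
                       nu_omega = 2, sparsity = 0.1, mu_sd = 2,
                       potts_sweeps = 30L) {
  if (!is.null(batch_effects)) {
    preset <- batch_preset(batch_effects)
    gamma_sd <- gamma_sd %||% preset$gamma_sd
    batch_scales <- batch_scales %||% preset$batch_scales
  }
  cfg <- list(B = as.integer(B), width = as.integer(width),
              height = as.integer(height), p = as.integer(p),
              d = as.integer(d), q = as.integer(q), eta = eta,
              gamma_sd = gamma_sd %||% 1.0,
              batch_scales = rep_len(batch_scales %||% c(3, 6), B),
              noise_level = noise_level, nu_omega = nu_omega,
              sparsity = sparsity, mu_sd = mu_sd,
              potts_sweeps = as.integer(potts_sweeps))
  if (cfg$d >= cfg$p) stop("latent dimension must be smaller than p")
  stopifnot(cfg$q >= 1, cfg$sparsity > 0, cfg$sparsity <= 1,
            cfg$noise_level >= 0, cfg$nu_omega > 0)
  cfg
}

# Exact pMOM sampler by rejection from N(0, 3 lambda1): the density ratio
# sqrt(3) u exp(-u/3) with u = l^2/lambda1 is bounded by 3 sqrt(3)/e.
rpmom <- function(n, lambda1) {
  out <- numeric(0)
  M <- 3 * sqrt(3) / exp(1)
  while (length(out) < n) {
    m <- (n - length(out)) * 2L + 10L
    x <- rnorm(m, 0, sqrt(3 * lambda1))
    u <- x^2 / lambda1
    acc <- runif(m) < sqrt(3) * u * exp(-u / 3) / M
    out <- c(out, x[acc])
  }
  out[seq_len(n)]
}

#' Simulate a multi-slice dataset with full ground truth
#'
#' Per slice: domain labels from [sample_potts()]; per-spot precisions
#' `omega ~ Gamma(nu/2, nu/2)`; factor scores `f | c = k ~ N(mu_k,
#' omega^{-1} Lambda^{-1})` (marginally Student-t); shared sparse loadings
#' with slab entries drawn from the pMOM density; additive effects
#' `gamma_b ~ N(0, gamma_sd^2)` recentred so the spot-weighted cross-batch
#' mean is zero (the additive effects are contrasts between batches, which is
#' what remains identifiable after gene centering); per-gene noise precisions
#' `t_bj = batch_scales_b * LogNormal(0, 0.25) / noise_level^2`; and
#' observations `y = L f + gamma_b + eps`.
#'
#' @param cfg configuration from [sim_config()].
#' @param seed integer seed; the same seed reproduces the dataset bit for
#'   bit.
#' @return list with `dataset` (an `st_dataset`, expression already on the
#'   normalized scale, platform `"ST"`) and `truth` (class `sim_truth`:
#'   `L`, `gamma`, `Tt`, `mu`, `Lambda`, `labels`, `omega`, `f`, `x`).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  p <- cfg$p; d <- cfg$d; q <- cfg$q; B <- cfg$B
  # ground-truth parameters shared across slices
  mu <- matrix(rnorm(d * q, 0, cfg$mu_sd), d, q)
  Lambda <- diag(1, d)
  mask <- matrix(runif(p * d) < cfg$sparsity, p, d)
  L <- matrix(0, p, d)
  L[mask] <- rpmom(sum(mask), 0.871)
  gamma <- matrix(rnorm(p * B, 0, cfg$gamma_sd), p, B)
  nb <- rep(cfg$width * cfg$height, B)
  gamma <- gamma - (gamma %*% nb) %*% t(rep(1, B)) / sum(nb)  # contrasts
  Tt <- matrix(0, p, B)
  for (b in seq_len(B)) {
    Tt[, b] <- cfg$batch_scales[b] * exp(rnorm(p, 0, 0.25))
    if (cfg$noise_level > 0) Tt[, b] <- Tt[, b] / cfg$noise_level^2
  }
  Uinv <- solve(chol(Lambda))                    # Lambda^{-1} = Uinv %*% t(Uinv)
  slices <- vector("list", B)
  labels <- list(); omegas <- list(); fs <- list(); xs <- list()
  potts_seeds <- sample.int(.Machine$integer.max, B)
  for (b in seq_len(B)) {
    grid <- sample_potts(cfg$width, cfg$height, q, cfg$eta,
                         n_sweeps = cfg$potts_sweeps, seed = potts_seeds[b])
    lab <- as.vector(grid)
    n <- length(lab)
    coords <- cbind(x = rep(seq_len(cfg$width), each = cfg$height),
                    y = rep(seq_len(cfg$height), cfg$width))
    om <- rgamma(n, shape = cfg$nu_omega / 2, rate = cfg$nu_omega / 2)
    Z <- matrix(rnorm(n * d), n, d)
    f <- t(mu)[lab, , drop = FALSE] + (Z %*% t(Uinv)) / sqrt(om)
    x <- f %*% t(L)
    y <- sweep(x, 2, gamma[, b], "+")
    if (cfg$noise_level > 0) {
      eps <- matrix(rnorm(n * p), n, p) /
        matrix(sqrt(Tt[, b]), n, p, byrow = TRUE)
      y <- y + eps
    }
    rownames(y) <- paste0("s", b, "_", seq_len(n))
    colnames(y) <- paste0("g", seq_len(p))
    rownames(coords) <- rownames(y)
    slices[[b]] <- slice_data(coords = coords, platform = "ST",
                              batch_id = paste0("slice", b), expr = y)
    labels[[b]] <- lab; omegas[[b]] <- om; fs[[b]] <- f; xs[[b]] <- x
  }
  dataset <- assemble_dataset(slices)
  truth <- structure(
    list(L = L, gamma = gamma, Tt = Tt, mu = mu, Lambda = Lambda,
         labels = unlist(labels), omega = unlist(omegas),
         f = do.call(rbind, fs), x = do.call(rbind, xs),
         geometry = list(width = cfg$width, height = cfg$height, B = B),
         cfg = cfg, seed = seed),
    class = "sim_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> B = %d, n = %d, p = %d, d = %d, q = %d\n",
              x$geometry$B, length(x$labels), nrow(x$L), ncol(x$L),
              ncol(x$mu)))
  invisible(x)
}

#' Write simulation ground truth as plain CSV files
#'
#' @param truth a `sim_truth`.
#' @param dir output directory.
#' @param barcodes optional per-spot barcodes (global-index order) stored in
#'   `labels.csv` so the file can be scored against run outputs directly.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir, barcodes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(truth$L, file.path(dir, "L.csv"), row.names = FALSE)
  write.csv(truth$gamma, file.path(dir, "gamma.csv"), row.names = FALSE)
  write.csv(truth$Tt, file.path(dir, "T.csv"), row.names = FALSE)
  write.csv(truth$mu, file.path(dir, "mu.csv"), row.names = FALSE)
  write.csv(truth$Lambda, file.path(dir, "Lambda.csv"), row.names = FALSE)
  lab <- data.frame(label = truth$labels, omega = truth$omega)
  if (!is.null(barcodes)) lab <- cbind(barcode = barcodes, lab)
  write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
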