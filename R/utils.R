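# Small internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  # both -Inf -> -Inf, avoid NaN from -Inf - -Inf
  out[is.infinite(a) & is.infinite(b) & a < 0 & b < 0] <- -Inf
  out
}

# Cholesky with diagonal jitter escalation; used wherever an SPD matrix is
# required but finite-sample scatter may be rank-deficient.
#' @noRd
chol_safe <- function(S, jitter = 1e-8, max_tries = 6L) {
  S <- (S + t(S)) / 2
  for (i in seq_len(max_tries)) {
    U <- tryCatch(chol(S), error = function(e) NULL)
    if (!is.null(U)) return(U)
    S <- S + diag(jitter, nrow(S))
    jitter <- jitter * 10
  }
  stop("matrix is not positive definite even after jitter", call. = FALSE)
}

#' @noRd
logdet_spd <- function(S) 2 * sum(log(diag(chol_safe(S))))

# log density of N_d(x; mean, Sigma)
#' @noRd
dmvnorm_log <- function(x, mean, Sigma) {
  d <- length(x)
  U <- chol_safe(Sigma)
  z <- backsolve(U, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(z^2)
}

# log density of the Wishart W_d(df, Scale) evaluated at SPD matrix W,
# density proportional to |W|^{(df-d-1)/2} exp(-tr(Scale^{-1} W)/2).
#' @noRd
dwishart_log <- function(W, df, Scale) {
  d <- nrow(W)
  stopifnot(df > d - 1)
  lmgamma <- (d * (d - 1) / 4) * log(pi) + sum(lgamma((df + 1 - seq_len(d)) / 2))
  0.5 * (df - d - 1) * logdet_spd(W) -
    0.5 * sum(diag(solve(Scale, W))) -
    0.5 * df * d * log(2) - 0.5 * df * logdet_spd(Scale) - lmgamma
}

#' @noRd
clip <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Rowwise squared Mahalanobis distances (x_i - mu_k)' Lambda (x_i - mu_k)
# for every row of F against every column of mu; returns n x q matrix.
#' @noRd
mahalanobis_sq <- function(F, mu, Lambda) {
  FL <- F %*% Lambda                      # n x d
  quad_f <- rowSums(FL * F)               # f' Lambda f
  cross <- FL %*% mu                      # n x q
  quad_mu <- colSums(mu * (Lambda %*% mu))
  sweep(-2 * cross, 2, quad_mu, "+") + quad_f
}

#' @noRd
msg_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
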