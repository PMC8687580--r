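# Independent oracles and random-instance builders shared across tests.

# Random network with recurrent matrix rescaled to a given spectral radius.
random_net <- function(N, M, rho = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(rnorm(N * M, 0, 0.8), N, M)
  K <- matrix(rnorm(N * N, 0, 0.3), N, N)
  if (rho > 0) K <- K * rho / spectral_radius(K) else K[] <- 0
  theta <- rnorm(N, 0, 0.3)
  network_params(W, K, theta)
}

# Symmetric rank-one recurrent matrix with spectral radius rho.
rank_one_K <- function(N, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- runif(N, 0.2, 1)
  rho * (v %o% v) / sum(v^2)
}

# Network pinned at the maximum-gain point: with x = 0 and
# theta = K %*% 0.5 the state s = 1/2 solves the fixed-point equation with
# h = 0, so every gain equals exactly 1/4. W is random full-rank (it does
# not enter h at x = 0 but keeps the Jacobian chi well defined).
max_gain_net <- function(K, M = 2) {
  N <- nrow(K)
  network_params(matrix(rnorm(N * M, 0, 0.5), N, M), K,
                 theta = drop(K %*% rep(0.5, N)))
}

# Central finite differences of the regularized objective with respect to
# every entry of W, K and theta. Deliberately brute-force and independent
# of the analytic gradient path.
fd_gradients <- function(params, x, config, h = 1e-6, newton_tol = 1e-13) {
  obj <- function(p) em_objective(p, x, config, newton_tol = newton_tol)$total
  N <- params$N; M <- params$M
  fdW <- matrix(0, N, M)
  for (i in seq_len(N)) for (j in seq_len(M)) {
    pp <- params; pp$W[i, j] <- pp$W[i, j] + h
    pm <- params; pm$W[i, j] <- pm$W[i, j] - h
    fdW[i, j] <- (obj(pp) - obj(pm)) / (2 * h)
  }
  fdK <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    pp <- params; pp$K[i, j] <- pp$K[i, j] + h
    pm <- params; pm$K[i, j] <- pm$K[i, j] - h
    fdK[i, j] <- (obj(pp) - obj(pm)) / (2 * h)
  }
  fdT <- numeric(N)
  for (i in seq_len(N)) {
    pp <- params; pp$theta[i] <- pp$theta[i] + h
    pm <- params; pm$theta[i] <- pm$theta[i] - h
    fdT[i] <- (obj(pp) - obj(pm)) / (2 * h)
  }
  list(W = fdW, K = fdK, T = fdT)
}

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))

# Power-iteration estimate of the dominant eigenvalue modulus (used on
# symmetric matrices, where the dominant eigenvalue is real).
power_iteration <- function(K, iters = 500L) {
  v <- rep(1, nrow(K)) / sqrt(nrow(K))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- drop(K %*% v)
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(0)
    v <- w / lam
  }
  abs(drop(crossprod(v, K %*% v)))
}
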