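#' Logistic activation and its derivatives
#'
#' `g(h) = 1 / (1 + exp(-h))`, with `g' = g (1 - g)` and
#' `g'' = g (1 - g) (1 - 2 g)`, evaluated elementwise. Saturates cleanly for
#' large |h| (no overflow).
#'
#' @param h net-input vector.
#' @return numeric vector of the same length.
#' @export
activation <- function(h) stats::plogis(h)

#' @rdname activation
#' @export
activation_deriv <- function(h) {
  g <- stats::plogis(h)
  g * (1 - g)
}

#' @rdname activation
#' @export
activation_second_deriv <- function(h) {
  g <- stats::plogis(h)
  g * (1 - g) * (1 - 2 * g)
}

#' Recurrent network parameters
#'
#' Container for the rate network
#' `tau ds/dt = -s + g(W x + K s - theta)` with M input channels and N
#' output neurons (overcomplete when N > M).
#'
#' @param W feed-forward weight matrix, N x M.
#' @param K recurrent weight matrix, N x N (defaults to zero).
#' @param theta threshold vector, length N (recycled from a scalar).
#' @param tau time constant (arbitrary units).
#' @return an object of class `network_params`.
#' @export
network_params <- function(W, K = NULL, theta = 0, tau = 1) {
  W <- as.matrix(W)
  N <- nrow(W)
  M <- ncol(W)
  if (is.null(K)) K <- matrix(0, N, N)
  K <- as.matrix(K)
  stopifnot(nrow(K) == N, ncol(K) == N, tau > 0)
  theta <- rep_len(as.numeric(theta), N)
  structure(list(W = W, K = K, theta = theta, tau = tau, M = M, N = N),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params> N = %d output neurons, M = %d input channels, tau = %g\n",
              x$N, x$M, x$tau))
  cat(sprintf("  spectral radius rho(K) = %.4f\n", spectral_radius(x$K)))
  invisible(x)
}

# Assemble a steady-state result from a state vector.
make_steady_state <- function(params, x, s, method, iterations, converged) {
  h <- drop(params$W %*% x + params$K %*% s - params$theta)
  g <- stats::plogis(h)
  structure(list(s = s, h = h, gain = g * (1 - g),
                 method = method, iterations = iterations,
                 converged = converged,
                 residual = max(abs(s - g))),
            class = "steady_state")
}

#' Steady state by Newton-Raphson
#'
#' Solves the fixed-point equation `s = g(W x + K s - theta)` by damping-free
#' Newton iteration `s <- s - (I - G K)^{-1} (s - g(h))`, where
#' `G = diag(g'(h))`. Convergence is judged on the infinity norm of the
#' fixed-point residual. A singular Newton system or exhausted iteration
#' budget yields `converged = FALSE`, never an error.
#'
#' @param params a [network_params()].
#' @param x input vector of length M.
#' @param s_init initial activity; defaults to the recurrence-free response
#'   `g(W x - theta)`.
#' @param tol infinity-norm residual tolerance.
#' @param max_iter iteration budget.
#' @return an object of class `steady_state` with fields `s`, `h`, `gain`,
#'   `method`, `iterations`, `converged`, `residual`.
#' @export
steady_state_newton <- function(params, x, s_init = NULL,
                                tol = 1e-10, max_iter = 200L) {
  stopifnot(length(x) == params$M)
  b <- drop(params$W %*% x - params$theta)
  s <- if (is.null(s_init)) stats::plogis(b) else s_init
  I_N <- diag(params$N)
  iter <- 0L
  repeat {
    h <- b + drop(params$K %*% s)
    g <- stats::plogis(h)
    f <- s - g
    if (max(abs(f)) <= tol) {
      return(make_steady_state(params, x, s, "newton", iter, TRUE))
    }
    if (iter >= max_iter) {
      return(make_steady_state(params, x, s, "newton", iter, FALSE))
    }
    gp <- g * (1 - g)
    J <- I_N - gp * params$K   # row-scales K by gp: (I - G K)
    delta <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      return(make_steady_state(params, x, s, "newton", iter, FALSE))
    }
    s <- s - delta
    # keep iterates in the open unit cube; g maps there anyway
    s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
    iter <- iter + 1L
  }
}

#' Explicit Euler integration of the rate dynamics
#'
#' Integrates `tau ds/dt = -s + g(W x + K s - theta)` with step `dt` until
#' the per-step change criterion `max |delta s| < tol` is met or the step
#' budget is exhausted. The returned step count is the convergence-time
#' measure used in the scaling sweeps (critical slowing down).
#'
#' @param params a [network_params()].
#' @param x input vector.
#' @param s0 initial state; defaults to `g(W x - theta)`.
#' @param dt time step (in units of `tau = 1` by default).
#' @param tol per-step infinity-norm change criterion.
#' @param max_steps step budget; exhausting it flags non-convergence.
#' @return list with `s` (final state), `n_steps`, `converged`.
#' @export
integrate_euler <- function(params, x, s0 = NULL, dt = 0.1,
                            tol = 1e-6, max_steps = 1e6) {
  stopifnot(dt > 0, length(x) == params$M)
  b <- drop(params$W %*% x - params$theta)
  s <- if (is.null(s0)) stats::plogis(b) else s0
  r <- dt / params$tau
  for (t in seq_len(max_steps)) {
    ds <- r * (-s + stats::plogis(b + drop(params$K %*% s)))
    if (max(abs(ds)) < tol) {
      return(list(s = s, n_steps = t - 1L, converged = TRUE))
    }
    s <- s + ds
  }
  list(s = s, n_steps = as.integer(max_steps), converged = FALSE)
}

#' Steady state with stability check and Euler fallback
#'
#' Runs Newton-Raphson first; if the solve fails, or `check_stability` is
#' set and the Newton fixed point is linearly unstable (some eigenvalue of
#' `I - G K` has non-positive real part), falls back to Euler integration
#' from `s_init`. In the supercritical regime this is what lands on the
#' stable symmetry-broken attractor instead of the unstable homogeneous
#' point.
#'
#' @inheritParams steady_state_newton
#' @param check_stability whether to eigen-test the Newton fixed point
#'   (costs one N x N eigendecomposition).
#' @param dt,euler_tol,max_steps Euler fallback settings.
#' @return a `steady_state`; `method` records which path produced it.
#' @export
steady_state <- function(params, x, s_init = NULL, tol = 1e-10,
                         max_iter = 200L, check_stability = FALSE,
                         dt = 0.1, euler_tol = 1e-6, max_steps = 1e6) {
  st <- steady_state_newton(params, x, s_init, tol = tol, max_iter = max_iter)
  ok <- st$converged
  if (ok && check_stability) {
    ev <- eigen(linearized_matrix(params, st), only.values = TRUE)$values
    ok <- min(Re(ev)) > 0
  }
  if (ok) return(st)
  eu <- integrate_euler(params, x, s0 = s_init, dt = dt,
                        tol = euler_tol, max_steps = max_steps)
  out <- make_steady_state(params, x, eu$s, "newton-then-euler", eu$n_steps,
                           eu$converged)
  out
}

#' Linearized dynamics matrix at a steady state
#'
#' Returns `I - G K` with `G = diag(g'(h))` evaluated at the steady state.
#' The fixed point is linearly stable iff all eigenvalues have positive
#' real part; since `max g' = 1/4`, stability is guaranteed whenever the
#' spectral radius of K is below 4.
#'
#' @param params a [network_params()].
#' @param steady a `steady_state`.
#' @return an N x N matrix.
#' @export
linearized_matrix <- function(params, steady) {
  diag(params$N) - steady$gain * params$K
}

#' Spectral radius of a square matrix
#'
#' @param K square matrix.
#' @return the maximum eigenvalue modulus.
#' @export
spectral_radius <- function(K) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K))
  max(Mod(eigen(K, only.values = TRUE)$values))
}

#' Save / load network checkpoints
#'
#' Serializes a `network_params` together with a metadata record (seed,
#' training phase, free-form notes) for bit-exact round-trips between
#' analysis steps.
#'
#' @param params a [network_params()].
#' @param path file path.
#' @param meta named list of metadata stored alongside the arrays.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   the `network_params` with a `meta` attribute.
#' @export
write_network <- function(params, path, meta = list()) {
  stopifnot(inherits(params, "network_params"))
  saveRDS(list(params = params, meta = meta), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- readRDS(path)
  out <- obj$params
  attr(out, "meta") <- obj$meta
  out
}
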