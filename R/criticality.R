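#' Population vector magnitude
#'
#' Modulus of the complex mean `1/N sum_k s_k exp(i phi_k)` with angles
#' `phi_k = 2 pi k / N` over the output index. Zero for uniform activity;
#' positive for symmetry-broken (bump-like) profiles.
#'
#' @param s activity vector.
#' @return a nonnegative scalar.
#' @export
population_vector_magnitude <- function(s) {
  N <- length(s)
  phi <- 2 * pi * seq_len(N) / N
  Mod(mean(s * exp(1i * phi)))
}

#' Mean squared pairwise correlation of responses
#'
#' Pearson correlation across samples for every unordered pair of output
#' neurons, squared and averaged. Neurons with zero variance across the
#' sample set are excluded (their correlation is undefined); the number
#' excluded is reported as an attribute.
#'
#' @param responses samples x N matrix of steady-state activities.
#' @return scalar in \[0, 1\] with attribute `n_excluded`.
#' @export
mean_squared_pairwise_correlation <- function(responses) {
  responses <- as.matrix(responses)
  if (nrow(responses) < 2) stop("need at least 2 samples")
  v <- apply(responses, 2, stats::var)
  keep <- which(v > 0)
  if (length(keep) < 2) stop("fewer than 2 neurons with nonzero variance")
  C <- stats::cor(responses[, keep, drop = FALSE])
  out <- mean(C[upper.tri(C)]^2)
  attr(out, "n_excluded") <- ncol(responses) - length(keep)
  out
}

#' Euler convergence time
#'
#' Number of Euler time-steps until the per-step change criterion is met,
#' starting from the recurrence-free response `g(W x - theta)`. Diverges
#' near the critical point (critical slowing down).
#'
#' @param params a [network_params()].
#' @param x input vector.
#' @param dt,tol,max_steps Euler settings (see [integrate_euler()]).
#' @return list with `n_steps` and `converged`.
#' @export
convergence_time <- function(params, x, dt = 0.1, tol = 1e-6,
                             max_steps = 1e6) {
  res <- integrate_euler(params, x, s0 = NULL, dt = dt, tol = tol,
                         max_steps = max_steps)
  list(n_steps = res$n_steps, converged = res$converged)
}

#' Scaling sweep of the recurrent connectivity
#'
#' Replaces the trained recurrent matrix by `sigma * K` over a grid of
#' scaling factors and evaluates four global measures at each scale:
#' the entropy term of the objective (no regularization) on a fixed
#' evaluation set; the Euler convergence time on the silent (zero) input;
#' the population-vector magnitude of the silent-input attractor (reached
#' by Euler from a weakly noise-perturbed homogeneous state, so symmetry
#' breaking is visible); and the mean squared pairwise correlation of the
#' steady-state responses to the evaluation set. The critical scale is
#' `4 / rho(K)`; the operating point is `sigma = 1`.
#'
#' @param params a trained [network_params()].
#' @param eval_stimuli samples x M matrix of evaluation stimuli (drawn once,
#'   reused across scales and across pre/post comparisons).
#' @param sigma_grid scaling factors; defaults to 60 log-spaced points in
#'   `[0.05, 1.5 * critical_sigma]`.
#' @param dt,euler_tol Euler settings for the time/attractor measures.
#' @param max_steps Euler step budget per scale.
#' @param attractor_noise magnitude of the uniform perturbation seeding the
#'   silent-input attractor search.
#' @return a data frame (class `sweep_report`) with one row per sigma and
#'   columns `sigma`, `rho_K`, `objective_noreg`, `convergence_time`,
#'   `popvec_magnitude`, `mean_sq_correlation`; attributes `critical_sigma`
#'   and `operating_point`. Per-scale failures yield `NA` entries.
#' @export
scale_sweep <- function(params, eval_stimuli, sigma_grid = NULL,
                        dt = 0.1, euler_tol = 1e-6, max_steps = 1e5,
                        attractor_noise = 1e-3) {
  eval_stimuli <- as.matrix(eval_stimuli)
  stopifnot(ncol(eval_stimuli) == params$M)
  rho_tr <- spectral_radius(params$K)
  critical_sigma <- 4 / rho_tr
  if (is.null(sigma_grid)) {
    sigma_grid <- exp(seq(log(0.05), log(1.5 * critical_sigma),
                          length.out = 60))
  }
  stopifnot(length(sigma_grid) >= 1)
  silent <- numeric(params$M)
  cfg0 <- learning_config(eta = 1, n_iterations = 0L, train_K = TRUE)
  n_eval <- nrow(eval_stimuli)
  rows <- vector("list", length(sigma_grid))
  for (g in seq_along(sigma_grid)) {
    sigma <- sigma_grid[g]
    p_s <- params
    p_s$K <- sigma * params$K
    # (i) entropy term on the eval set; NA on any per-sample failure
    obj <- tryCatch(em_objective(p_s, eval_stimuli, cfg0)$entropy,
                    error = function(e) NA_real_)
    # (ii) convergence time on the silent stimulus
    ct <- convergence_time(p_s, silent, dt = dt, tol = euler_tol,
                           max_steps = max_steps)
    # (iii) silent-input attractor and its population vector
    s0 <- stats::plogis(-p_s$theta) +
      stats::runif(p_s$N, 0, attractor_noise)
    att <- integrate_euler(p_s, silent, s0 = s0, dt = dt, tol = euler_tol,
                           max_steps = max_steps)
    pv <- if (att$converged) population_vector_magnitude(att$s) else NA_real_
    # (iv) pairwise correlations over the eval-set responses
    R <- matrix(NA_real_, n_eval, p_s$N)
    for (i in seq_len(n_eval)) {
      st <- steady_state(p_s, eval_stimuli[i, ], dt = dt,
                         euler_tol = euler_tol, max_steps = max_steps)
      if (st$converged) R[i, ] <- st$s
    }
    msc <- if (all(stats::complete.cases(R))) {
      tryCatch(as.numeric(mean_squared_pairwise_correlation(R)),
               error = function(e) NA_real_)
    } else {
      NA_real_
    }
    rows[[g]] <- data.frame(
      sigma = sigma,
      rho_K = sigma * rho_tr,
      objective_noreg = obj,
      convergence_time = if (ct$converged) ct$n_steps else NA_integer_,
      popvec_magnitude = pv,
      mean_sq_correlation = msc)
  }
  out <- do.call(rbind, rows)
  attr(out, "critical_sigma") <- critical_sigma
  attr(out, "operating_point") <- 1
  class(out) <- c("sweep_report", class(out))
  out
}
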