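#' Learning configuration
#'
#' Hyper-parameters for one training phase of the regularized
#' entropy-maximization rule. The objective is
#' `eps = -1/2 < log det(chi^T chi) >_x + reg(W) + reg(K)` with
#' `reg(A) = lambda * sum |A|` for the l1 norm and
#' `lambda / 2 * sum A^2` for the l2 norm.
#'
#' @param eta learning rate (> 0).
#' @param lambda_W,lambda_K regularization coefficients (>= 0).
#' @param ff_norm,rec_norm norm used to regularize the feed-forward and
#'   recurrent matrices ("l1" or "l2").
#' @param n_iterations number of online samples for the phase.
#' @param train_W,train_K,train_T which parameter blocks are updated; at
#'   least one must be `TRUE`.
#' @return an object of class `learning_config`.
#' @export
learning_config <- function(eta, lambda_W = 0, lambda_K = 0,
                            ff_norm = c("l1", "l2"),
                            rec_norm = c("l2", "l1"),
                            n_iterations = 1000L,
                            train_W = FALSE, train_K = TRUE,
                            train_T = FALSE) {
  ff_norm <- match.arg(ff_norm)
  rec_norm <- match.arg(rec_norm)
  stopifnot(eta > 0, lambda_W >= 0, lambda_K >= 0, n_iterations >= 0)
  if (!any(train_W, train_K, train_T)) {
    stop("at least one of train_W, train_K, train_T must be TRUE")
  }
  structure(list(eta = eta, lambda_W = lambda_W, lambda_K = lambda_K,
                 ff_norm = ff_norm, rec_norm = rec_norm,
                 n_iterations = as.integer(n_iterations),
                 train_W = train_W, train_K = train_K, train_T = train_T),
            class = "learning_config")
}

#' Input-output Jacobian of the steady state
#'
#' For a converged steady state, `phi = (I - G K)^{-1} G` and the Jacobian
#' of the transformation is `chi = d s / d x = phi W` (N x M).
#'
#' @param params a [network_params()].
#' @param steady a converged `steady_state`.
#' @return list with matrices `phi` (N x N) and `chi` (N x M).
#' @export
jacobian_chi <- function(params, steady) {
  if (!steady$converged) stop("steady state did not converge")
  A <- diag(params$N) - steady$gain * params$K
  phi <- tryCatch(solve(A, diag(steady$gain, params$N)),
                  error = function(e) NULL)
  if (is.null(phi) || any(!is.finite(phi))) {
    stop("linearized matrix (I - G K) is singular: network at criticality")
  }
  list(phi = phi, chi = phi %*% params$W)
}

# sign with sign(0) = 0 (l1 subgradient choice)
sgn <- function(A) sign(A)

reg_value <- function(A, lambda, norm) {
  if (lambda == 0) return(0)
  if (norm == "l1") lambda * sum(abs(A)) else lambda / 2 * sum(A^2)
}

reg_grad <- function(A, lambda, norm) {
  if (norm == "l1") lambda * sgn(A) else lambda * A
}

# Entropy payoff -1/2 log det(chi^T chi) for a single sample, given chi.
entropy_term_from_chi <- function(chi) {
  d <- determinant(crossprod(chi), logarithm = TRUE)
  if (d$sign <= 0 || !is.finite(d$modulus)) {
    stop("chi^T chi is singular or indefinite: rank-deficient Jacobian")
  }
  -0.5 * as.numeric(d$modulus)
}

#' Regularized entropy-maximization objective
#'
#' Evaluates `eps = -1/2 < log det(chi^T chi) >_x + reg(W) + reg(K)` over a
#' batch of stimuli, solving the fixed-point equation afresh for each
#' sample.
#'
#' @param params a [network_params()].
#' @param X a single input vector or a (samples x M) matrix.
#' @param config a [learning_config()] supplying the regularization.
#' @param newton_tol,max_iter steady-state solver settings.
#' @return list with `total`, `entropy`, `reg_W`, `reg_K`.
#' @export
em_objective <- function(params, X, config, newton_tol = 1e-12,
                         max_iter = 200L) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(nrow(X) >= 1, ncol(X) == params$M)
  ent <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    st <- steady_state_newton(params, X[i, ], tol = newton_tol,
                              max_iter = max_iter)
    if (!st$converged) stop("steady-state solve failed for sample ", i)
    jac <- jacobian_chi(params, st)
    ent[i] <- tryCatch(entropy_term_from_chi(jac$chi),
                       error = function(e) {
                         stop("rank-deficient Jacobian for sample ", i)
                       })
  }
  reg_W <- reg_value(params$W, config$lambda_W, config$ff_norm)
  reg_K <- reg_value(params$K, config$lambda_K, config$rec_norm)
  list(total = mean(ent) + reg_W + reg_K,
       entropy = mean(ent), reg_W = reg_W, reg_K = reg_K)
}

#' Analytic gradients of the regularized objective
#'
#' Single-sample gradients of the objective with respect to W, K and theta,
#' derived by implicit differentiation of the fixed point:
#' with `phi = (I - G K)^{-1} G`, `chi = phi W`,
#' `chi^+ = (chi^T chi)^{-1} chi^T` (overcomplete pseudo-inverse) and the
#' curvature vector `y_l = (chi chi^+ phi)_ll g''(h_l) / g'(h_l)^3`, the
#' entropy-payoff gradients are
#' `phi^T ((chi^+)^T + y x^T)` for W, `phi^T (chi chi^+ + y s^T)` for K and
#' `-phi^T y` for theta. The returned `dW`, `dK`, `dT` are gradients of the
#' *objective* (payoff negated plus regularization), i.e. the descent
#' update is `A <- A - eta * dA`.
#'
#' @param params a [network_params()].
#' @param x input vector.
#' @param steady the converged `steady_state` for `x`.
#' @param config a [learning_config()].
#' @return list with `dW` (N x M), `dK` (N x N), `dT` (length N), and the
#'   intermediates `phi`, `chi`, `y`.
#' @export
em_gradients <- function(params, x, steady, config) {
  jac <- jacobian_chi(params, steady)
  phi <- jac$phi
  chi <- jac$chi
  A <- crossprod(chi)                       # M x M Gram matrix
  chip <- tryCatch(solve(A, t(chi)), error = function(e) NULL)
  if (is.null(chip)) stop("chi is rank-deficient; cannot form pseudo-inverse")
  P <- chi %*% chip                         # N x N projector chi chi^+
  gp <- steady$gain
  gpp <- gp * (1 - 2 * steady$s)            # g'' at the steady state
  y <- rowSums(P * t(phi)) * gpp / gp^3     # diag(chi chi^+ phi) weighting
  dW <- -crossprod(phi, t(chip) + outer(y, x)) +
    reg_grad(params$W, config$lambda_W, config$ff_norm)
  dK <- -crossprod(phi, P + outer(y, steady$s)) +
    reg_grad(params$K, config$lambda_K, config$rec_norm)
  dT <- drop(crossprod(phi, y))
  list(dW = dW, dK = dK, dT = dT, phi = phi, chi = chi, y = y)
}

#' Tonotopically ordered feed-forward initialization
#'
#' Row i of W is a weak Gaussian bump centered at channel `i * M / N`, so
#' that preferred frequencies are ordered along the output index; thresholds
#' start at a constant.
#'
#' @param M,N input and output dimensions (N >= M).
#' @param amplitude bump height.
#' @param width bump width in channel units.
#' @param theta0 initial threshold value.
#' @return list with `W` (N x M) and `theta` (length N).
#' @export
init_feedforward_tonotopic <- function(M, N, amplitude = 0.5, width = 1,
                                       theta0 = 0) {
  stopifnot(N >= M, width > 0)
  k <- seq_len(M)
  W <- matrix(0, N, M)
  for (i in seq_len(N)) {
    W[i, ] <- amplitude * exp(-(k - i * M / N)^2 / (2 * width^2))
  }
  list(W = W, theta = rep(theta0, N))
}

#' Online training of one phase
#'
#' Plain stochastic gradient descent on the regularized objective, one
#' sample at a time. Frozen blocks (per the config's `train_*` flags) are
#' untouched; the diagonal of K (autapses) is truncated to zero after every
#' update. Samples whose steady-state solve or Jacobian fails are skipped
#' and counted; the run aborts if more than 1% of samples fail within any
#' 10,000-sample window.
#'
#' @param params a [network_params()].
#' @param config a [learning_config()].
#' @param stim_fun zero-argument function returning one (already
#'   attenuated, normalized) input vector per call.
#' @param trace_every cadence (in samples) at which the per-sample entropy
#'   term, regularization terms and rho(K) are recorded; 0 disables tracing.
#' @param newton_tol,max_iter steady-state solver settings used in
#'   training.
#' @return list with the updated `params`, a `trace` data frame and the
#'   total `n_failures`.
#' @export
train_phase <- function(params, config, stim_fun, trace_every = 1000L,
                        newton_tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(params, "network_params"),
            inherits(config, "learning_config"))
  n <- config$n_iterations
  eta <- config$eta
  trace <- list()
  failures <- 0L
  window_failures <- 0L
  for (it in seq_len(n)) {
    if (it %% 10000L == 1L) window_failures <- 0L
    x <- stim_fun()
    st <- steady_state_newton(params, x, tol = newton_tol,
                              max_iter = max_iter)
    grads <- if (st$converged) {
      tryCatch(em_gradients(params, x, st, config), error = function(e) NULL)
    } else {
      NULL
    }
    if (is.null(grads)) {
      failures <- failures + 1L
      window_failures <- window_failures + 1L
      if (window_failures > 100L) {
        stop("more than 1% of steady-state solves failed within a ",
             "10,000-sample window; network likely supercritical")
      }
      next
    }
    if (config$train_W) params$W <- params$W - eta * grads$dW
    if (config$train_T) params$theta <- params$theta - eta * grads$dT
    if (config$train_K) {
      dK <- grads$dK
      diag(dK) <- 0                       # autapse truncation
      params$K <- params$K - eta * dK
      diag(params$K) <- 0
    }
    if (trace_every > 0 && (it %% trace_every == 0L || it == n)) {
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = it,
        entropy = entropy_term_from_chi(grads$chi),
        reg_W = reg_value(params$W, config$lambda_W, config$ff_norm),
        reg_K = reg_value(params$K, config$lambda_K, config$rec_norm),
        rho_K = spectral_radius(params$K),
        failures = failures)
    }
  }
  list(params = params,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(iteration = integer(), entropy = numeric(),
                    reg_W = numeric(), reg_K = numeric(),
                    rho_K = numeric(), failures = integer()),
       n_failures = failures)
}

#' The standard three-phase training schedule
#'
#' Builds the phase list executed by [run_schedule()]: phase 1 trains W and
#' theta on unattenuated inputs with K held at zero; phase 2 trains K alone
#' on unattenuated inputs; phase 3 continues exactly as phase 2 but with
#' attenuated inputs (the sensory-deprivation phase). A variant that skips
#' phase 2 (no recurrent pretraining) is obtained with
#' `include_phase2 = FALSE`.
#'
#' @param attenuation an `attenuation_profile` applied in phase 3.
#' @param iters_1,iters_2,iters_3 per-phase sample counts.
#' @param eta_1 phase-1 learning rate; `eta_23` is shared by phases 2-3.
#' @param lambda_W,lambda_K regularization coefficients.
#' @param rec_norm recurrent regularization norm ("l2" default, "l1"
#'   variant available).
#' @param include_phase2 whether to pretrain K on unattenuated inputs.
#' @return list of phases, each a list with `config` and `attenuation`.
#' @export
default_schedule <- function(attenuation,
                             iters_1 = 50000L, iters_2 = 1000000L,
                             iters_3 = 1000000L,
                             eta_1 = 0.1, eta_23 = 0.001,
                             lambda_W = 0.001, lambda_K = 0.226,
                             rec_norm = "l2",
                             include_phase2 = TRUE) {
  phase1 <- list(config = learning_config(eta = eta_1, lambda_W = lambda_W,
                                          ff_norm = "l1",
                                          n_iterations = iters_1,
                                          train_W = TRUE, train_K = FALSE,
                                          train_T = TRUE),
                 attenuation = NULL)
  phase2 <- list(config = learning_config(eta = eta_23, lambda_K = lambda_K,
                                          rec_norm = rec_norm,
                                          n_iterations = iters_2,
                                          train_K = TRUE),
                 attenuation = NULL)
  phase3 <- list(config = learning_config(eta = eta_23, lambda_K = lambda_K,
                                          rec_norm = rec_norm,
                                          n_iterations = iters_3,
                                          train_K = TRUE),
                 attenuation = attenuation)
  if (include_phase2) list(phase1, phase2, phase3) else list(phase1, phase3)
}

#' Run a training schedule
#'
#' Executes the phases in order, drawing stimuli from `model` (attenuated
#' per phase where requested) and returning the parameter checkpoint and
#' trace after every phase.
#'
#' @param params initial [network_params()].
#' @param phases list of phases as built by [default_schedule()].
#' @param model a calibrated [stimulus_model()].
#' @param trace_every trace cadence passed to [train_phase()].
#' @return list with `checkpoints` (list of `network_params`, one per
#'   phase) and `traces` (list of data frames).
#' @export
run_schedule <- function(params, phases, model, trace_every = 1000L) {
  checkpoints <- list()
  traces <- list()
  for (p in seq_along(phases)) {
    phase <- phases[[p]]
    att <- phase$attenuation
    stim_fun <- if (is.null(att)) {
      function() generate_stimulus(model)
    } else {
      function() apply_attenuation(generate_stimulus(model), att)
    }
    res <- train_phase(params, phase$config, stim_fun,
                       trace_every = trace_every)
    params <- res$params
    checkpoints[[p]] <- params
    traces[[p]] <- res$trace
  }
  list(checkpoints = checkpoints, traces = traces)
}
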