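test_that("the Jacobian reduces to closed forms and matches perturbation", {
  set.seed(1)
  p0 <- random_net(6, 3, rho = 0)
  x <- runif(3, 0, 0.5)
  st <- steady_state_newton(p0, x, tol = 1e-13)
  jac <- jacobian_chi(p0, st)
  expect_equal(jac$phi, diag(st$gain))
  expect_equal(jac$chi, st$gain * p0$W)
  # scalar network: chi = g' w / (1 - g' k)
  p1 <- network_params(matrix(0.7, 1, 1), matrix(0.9, 1, 1), theta = 0.2)
  st1 <- steady_state_newton(p1, 0.3, tol = 1e-13)
  gp <- st1$gain
  expect_equal(drop(jacobian_chi(p1, st1)$chi), gp * 0.7 / (1 - gp * 0.9))
  # chi against finite-difference d s / d x on an overcomplete net
  set.seed(2)
  p <- random_net(8, 4, rho = 2)
  x <- runif(4, 0, 0.5)
  st <- steady_state_newton(p, x, tol = 1e-13)
  chi <- jacobian_chi(p, st)$chi
  eps <- 1e-6
  for (j in 1:4) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    fd <- (steady_state_newton(p, xp, tol = 1e-13)$s -
           steady_state_newton(p, xm, tol = 1e-13)$s) / (2 * eps)
    expect_lt(max(abs(chi[, j] - fd)), 1e-6)
  }
})

test_that("the objective evaluates the scalar closed form and drops unused penalties", {
  p <- network_params(matrix(1, 1, 1), matrix(0, 1, 1), theta = 0)
  cfg <- learning_config(eta = 1, train_K = TRUE)
  obj <- em_objective(p, 0, cfg)
  # s = 1/2, chi = 1/4: the entropy term is -log(1/4)
  expect_equal(obj$entropy, -log(0.25), tolerance = 1e-10)
  expect_identical(obj$reg_W, 0)
  expect_identical(obj$reg_K, 0)
  expect_equal(obj$total, obj$entropy)
})

test_that("regularization contributes its exact gradient on top of the entropy term", {
  set.seed(3)
  p <- random_net(6, 3, rho = 2)
  x <- runif(3, 0, 0.5)
  st <- steady_state_newton(p, x, tol = 1e-13)
  g0 <- em_gradients(p, x, st, learning_config(eta = 1, train_K = TRUE))
  gl2 <- em_gradients(p, x, st, learning_config(eta = 1, lambda_K = 0.3,
                                                rec_norm = "l2", train_K = TRUE))
  expect_equal(gl2$dK - g0$dK, 0.3 * p$K)
  gl1 <- em_gradients(p, x, st, learning_config(eta = 1, lambda_W = 0.2,
                                                ff_norm = "l1", train_K = TRUE))
  expect_equal(gl1$dW - g0$dW, 0.2 * sign(p$W))
})

test_that("zero curvature at the maximum-gain state silences y and the threshold update", {
  K <- rank_one_K(8, 2, seed = 4)
  p <- max_gain_net(K)
  st <- steady_state_newton(p, numeric(2), s_init = rep(0.5, 8), tol = 1e-13)
  g <- em_gradients(p, numeric(2), st, learning_config(eta = 1, train_K = TRUE))
  expect_lt(max(abs(g$y)), 1e-10)   # g''(0) = 0
  expect_lt(max(abs(g$dT)), 1e-10)
})

test_that("analytic gradients match central finite differences of the objective", {
  # one representative instance per norm pairing; the ten-seed gate runs in
  # the acceptance suite
  for (norms in list(c("l1", "l2"), c("l2", "l1"))) {
    p <- random_net(6, 3, rho = 2, seed = 5)
    x <- runif(3, 0, 0.5)
    cfg <- learning_config(eta = 1, lambda_W = 0.01, lambda_K = 0.05,
                           ff_norm = norms[1], rec_norm = norms[2],
                           train_K = TRUE)
    st <- steady_state_newton(p, x, tol = 1e-13)
    g <- em_gradients(p, x, st, cfg)
    fd <- fd_gradients(p, x, cfg)
    expect_lt(rel_err(g$dW, fd$W), 1e-5)
    expect_lt(rel_err(g$dK, fd$K), 1e-5)
    expect_lt(rel_err(g$dT, fd$T), 1e-5)
  }
})

test_that("training enforces the config invariant, autapse truncation and freezes", {
  expect_error(learning_config(eta = 1, train_W = FALSE, train_K = FALSE,
                               train_T = FALSE),
               "at least one")
  set.seed(6)
  p <- random_net(8, 4, rho = 1)
  diag(p$K) <- 0
  m <- calibrate_normalization(stimulus_model(n_channels = 4), 200L)
  cfg <- learning_config(eta = 0.01, lambda_K = 0.05, n_iterations = 50L,
                         train_K = TRUE)
  res <- train_phase(p, cfg, function() generate_stimulus(m), trace_every = 0L)
  expect_identical(diag(res$params$K), rep(0, 8))
  expect_false(identical(res$params$K, p$K))
  expect_identical(res$params$W, p$W)       # frozen blocks untouched
  expect_identical(res$params$theta, p$theta)
})

test_that("training is reproducible from the seed", {
  m <- calibrate_normalization(stimulus_model(n_channels = 4), 200L)
  p <- random_net(6, 4, rho = 1, seed = 7)
  cfg <- learning_config(eta = 0.01, lambda_K = 0.05, n_iterations = 30L,
                         train_K = TRUE)
  set.seed(99)
  a <- train_phase(p, cfg, function() generate_stimulus(m), trace_every = 0L)
  set.seed(99)
  b <- train_phase(p, cfg, function() generate_stimulus(m), trace_every = 0L)
  expect_identical(a$params$K, b$params$K)
})

test_that("tonotopic initialization orders Gaussian bumps along the output index", {
  init0 <- init_feedforward_tonotopic(10, 30, amplitude = 0)
  expect_identical(init0$W, matrix(0, 30, 10))
  init <- init_feedforward_tonotopic(10, 30)
  pf <- preferred_frequency(init$W)
  expect_true(all(diff(pf) >= 0))
  centers <- seq_len(30) * 10 / 30
  expect_identical(pf, as.integer(round(pmin(pmax(centers, 1), 10))))
})

test_that("an empty schedule returns the initial parameters and phase 1 keeps K at zero", {
  set.seed(8)
  m <- calibrate_normalization(stimulus_model(n_channels = 4), 200L)
  init <- init_feedforward_tonotopic(4, 8)
  p0 <- network_params(init$W, theta = init$theta)
  empty <- run_schedule(p0, list(), m)
  expect_length(empty$checkpoints, 0)
  sched <- default_schedule(sigmoid_attenuation(2, 10, 4),
                            iters_1 = 50L, iters_2 = 20L, iters_3 = 20L)
  fit <- run_schedule(p0, sched, m, trace_every = 0L)
  expect_identical(fit$checkpoints[[1]]$K, matrix(0, 8, 8))
})

test_that("smoke-scale recurrent training converges and preserves tonotopy", {
  ex <- get_smoke_experiment()
  tr <- ex$traces[[2]]
  tot <- tr$entropy + tr$reg_W + tr$reg_K
  n <- length(tot)
  expect_lt(mean(tot[(n %/% 2 + 1):n]), mean(tot[1:(n %/% 4)]))
  pre <- ex$checkpoints[[2]]
  pf <- preferred_frequency(pre$W)
  expect_gt(cor(pf, seq_along(pf), method = "spearman"), 0.95)
  expect_identical(diag(pre$K), rep(0, pre$N))
  expect_identical(diag(ex$checkpoints[[3]]$K), rep(0, pre$N))
})

test_that("l1 recurrent regularization drives most connections to zero", {
  ex <- get_smoke_experiment()
  p1 <- ex$checkpoints[[1]]
  set.seed(5)
  cfg <- learning_config(eta = 0.001, lambda_K = 0.05, rec_norm = "l1",
                         n_iterations = 10000L, train_K = TRUE)
  res <- train_phase(p1, cfg, function() generate_stimulus(ex$model),
                     trace_every = 0L)
  K <- res$params$K
  offd <- K[row(K) != col(K)]
  quantum <- cfg$eta * cfg$lambda_K   # per-step l1 subgradient kick
  expect_gt(mean(abs(offd) < 10 * quantum), 0.9)
  expect_gt(max(abs(offd)), 100 * quantum)  # a few survivors stay strong
})
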