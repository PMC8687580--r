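test_that("activation derivatives match the logistic algebra and finite differences", {
  expect_equal(activation(0), 0.5)
  expect_equal(activation_deriv(0), 0.25)
  expect_equal(activation_second_deriv(0), 0)
  set.seed(1)
  h <- c(runif(50, -8, 8), -500, 500)
  eps <- 1e-5
  fd1 <- (activation(h + eps) - activation(h - eps)) / (2 * eps)
  expect_lt(max(abs(fd1 - activation_deriv(h))), 1e-8)
  fd2 <- (activation_deriv(h + eps) - activation_deriv(h - eps)) / (2 * eps)
  expect_lt(max(abs(fd2 - activation_second_deriv(h))), 1e-8)
  expect_true(all(is.finite(activation(c(-500, 500)))))
})

test_that("Newton solves recurrence-free and scalar networks exactly", {
  set.seed(2)
  p <- random_net(6, 3, rho = 0)
  x <- runif(3, 0, 0.5)
  st <- steady_state_newton(p, x)
  expect_true(st$converged)
  expect_identical(st$iterations, 0L)  # K = 0: the initializer is the answer
  expect_equal(st$s, drop(plogis(p$W %*% x - p$theta)))
  p1 <- network_params(matrix(0, 1, 1), matrix(0, 1, 1), theta = 0)
  expect_equal(steady_state_newton(p1, 0)$s, 0.5)
})

test_that("Newton and Euler agree on subcritical networks", {
  set.seed(3)
  p <- random_net(10, 5, rho = 2)
  x <- runif(5, 0, 0.5)
  st <- steady_state_newton(p, x, tol = 1e-13)
  eu <- integrate_euler(p, x, dt = 0.005, tol = 1e-12, max_steps = 1e6)
  expect_true(st$converged && eu$converged)
  expect_lt(max(abs(st$s - eu$s)), 1e-8)
})

test_that("steady states satisfy the fixed-point residual, bounds and gain cap", {
  for (seed in 1:10) {
    p <- random_net(8, 4, rho = runif(1, 0.5, 3), seed = seed)
    x <- runif(4, 0, 0.5)
    st <- steady_state_newton(p, x)
    expect_true(st$converged)
    expect_lte(st$residual, 1e-10)
    expect_true(all(st$s > 0 & st$s < 1))
    expect_true(all(st$gain > 0 & st$gain <= 0.25))
  }
})

test_that("Euler counts zero steps from a fixed point and slows near criticality", {
  set.seed(4)
  p <- random_net(8, 4, rho = 1.5)
  x <- runif(4, 0, 0.5)
  st <- steady_state_newton(p, x, tol = 1e-13)
  at_fp <- integrate_euler(p, x, s0 = st$s, tol = 1e-6)
  expect_identical(at_fp$n_steps, 0L)
  # critical slowing down: step count grows as K is scaled toward rho = 4
  K1 <- rank_one_K(12, 1, seed = 5)
  steps <- sapply(c(0.5, 2.0, 3.5), function(rho) {
    pr <- max_gain_net(rho * K1)
    integrate_euler(pr, numeric(2), s0 = rep(0.4, 12), tol = 1e-8)$n_steps
  })
  expect_true(all(diff(steps) > 0))
})

test_that("the linearized matrix tracks gain-scaled recurrence", {
  set.seed(6)
  p0 <- random_net(6, 3, rho = 0)
  st <- steady_state_newton(p0, runif(3, 0, 0.5))
  expect_equal(linearized_matrix(p0, st), diag(6))
  # at the maximum-gain state a rank-one K with rho = 4 sits exactly on
  # the stability boundary
  K4 <- rank_one_K(10, 4, seed = 7)
  p4 <- max_gain_net(K4)
  st4 <- steady_state_newton(p4, numeric(2), s_init = rep(0.5, 10))
  expect_true(st4$converged)
  expect_equal(st4$gain, rep(0.25, 10))
  ev <- eigen(linearized_matrix(p4, st4), only.values = TRUE)$values
  expect_lt(abs(min(Re(ev))), 1e-9)
})

test_that("spectral radius is homogeneous and matches power iteration", {
  N <- 9
  expect_equal(spectral_radius(matrix(3 / N, N, N)), 3)
  set.seed(8)
  A <- matrix(rnorm(N * N), N, N)
  S <- A + t(A)  # symmetric: dominant eigenvalue is real
  expect_equal(spectral_radius(2.5 * S), 2.5 * spectral_radius(S))
  expect_lt(abs(spectral_radius(S) - power_iteration(S)), 1e-8)
})

test_that("supercritical Newton failures fall back to Euler attractors", {
  # rho(K) > 4 at maximum gain: the homogeneous point is unstable and the
  # stability-checked solver must hand over to Euler
  K <- rank_one_K(12, 6, seed = 9)
  p <- max_gain_net(K)
  st <- steady_state(p, numeric(2), s_init = rep(0.5, 12) + runif(12, 0, 1e-3),
                     check_stability = TRUE, max_steps = 1e5)
  expect_match(st$method, "euler")
  expect_true(st$converged)
  # the Euler attractor is a genuine fixed point away from the unstable one
  expect_lt(st$residual, 1e-4)
})

test_that("network checkpoints round-trip bit-exactly", {
  set.seed(10)
  p <- random_net(5, 2, rho = 1)
  path <- tempfile(fileext = ".rds")
  write_network(p, path, meta = list(phase = 2, seed = 10))
  q <- read_network(path)
  expect_identical(q$W, p$W)
  expect_identical(q$K, p$K)
  expect_identical(q$theta, p$theta)
  expect_identical(attr(q, "meta")$phase, 2)
  unlink(path)
})
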