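test_that("preferred frequencies are row argmaxes with low-channel tie-breaks", {
  W <- rbind(exp(-(1:10 - 7)^2 / 2), c(1, 1, rep(0, 8)), rep(0, 10))
  expect_warning(pf <- preferred_frequency(W), "all-zero")
  expect_identical(pf[1], 7L)
  expect_identical(pf[2], 1L)   # tie broken toward the lowest channel
  expect_true(is.na(pf[3]))
})

test_that("aligned row profiles average by preferred-frequency offset", {
  N <- 8L
  K <- matrix(0.7, N, N)
  diag(K) <- 0
  prof <- aligned_row_profile(K, pref = 1:N)
  expect_true(all(abs(prof$mean - 0.7) < 1e-12))  # flat at the common value
  expect_identical(sum(prof$n), N * (N - 1L))
  expect_false(0 %in% prof$offset)  # distinct preferences, no autapses
})

test_that("zone classification follows the attenuation at the preferred frequency", {
  pf <- 1:40
  ones <- sigmoid_attenuation(k0 = 1, beta = -1e-9, M = 40)
  ones$values[] <- 1
  z1 <- classify_zones(pf, ones)
  expect_true(all(z1$zone == "non_deprived"))
  z2 <- classify_zones(pf, sigmoid_attenuation(k0 = 20, beta = 10, M = 40))
  expect_true(all(z2$zone[pf > 20] == "deprived"))
  expect_true(all(z2$zone[pf < 20] == "non_deprived"))
  z3 <- classify_zones(pf, band_attenuation(10, 30, 1, 40))
  expect_identical(which(z3$zone == "deprived"), 11:29)
})

test_that("an untrained recurrence-free network does not hallucinate", {
  set.seed(4)
  init <- init_feedforward_tonotopic(6, 18)
  p <- network_params(init$W, theta = init$theta)
  baseline <- steady_state_newton(p, numeric(6), tol = 1e-13)$s
  h <- hallucination_score(p, baseline)
  expect_lt(abs(h$score), 2e-3)
  expect_false(h$is_hallucinating)
  expect_true(h$converged)
})

test_that("audiogram bisection recovers a known linear threshold and brackets the criterion", {
  # near-linear scalar response: diff ~ g'(0) w a = 0.002 a -> threshold 5
  p <- network_params(matrix(0.008, 1, 1), matrix(0, 1, 1), theta = 0)
  ag <- simulate_audiogram(p)
  expect_false(ag$ceiling[1])
  expect_lt(abs(ag$threshold[1] - 5), 0.01)
  expect_lt(abs(ag$achieved_diff[1] - 0.01), 1e-4)
})

test_that("steady-state response grows monotonically with probe amplitude", {
  ex <- get_smoke_experiment()
  pre <- ex$checkpoints[[2]]
  silent <- steady_state_newton(pre, numeric(pre$M), tol = 1e-12)$s
  diffs <- sapply(c(0.01, 0.05, 0.2, 1), function(a) {
    st <- steady_state_newton(pre, pure_tone_probe(3, a, pre$M), tol = 1e-12)
    max(abs(st$s - silent))
  })
  expect_true(all(diff(diffs) > 0))
})

test_that("a schedule without a deprivation phase leaves the network unchanged", {
  set.seed(21)
  ex0 <- deprivation_experiment(M = 6L, N = 12L, iters_1 = 300L,
                                iters_2 = 300L, iters_3 = 0L,
                                lambda_K = 0.05, n_calibration = 300L,
                                n_eval = 25L, n_sigma = 6L,
                                sweep_max_steps = 5e3, audiogram = FALSE)
  expect_identical(ex0$checkpoints[[2]]$K, ex0$checkpoints[[3]]$K)
  expect_equal(ex0$critical_sigma_pre, ex0$critical_sigma_post)
})

test_that("deprivation reshapes recurrent profiles and raises correlations", {
  ex <- get_smoke_experiment()
  dep <- ex$profiles_post$deprived
  non <- ex$profiles_post$non_deprived
  expect_false(is.null(dep))
  # stronger central excitation among deprived neurons
  expect_gt(dep$mean[dep$offset == 0], non$mean[non$offset == 0])
  # pairwise correlations at the operating point rise after deprivation
  near_op <- function(sw) sw$mean_sq_correlation[which.min(abs(sw$sigma - 1))]
  expect_gt(near_op(ex$sweep_post), near_op(ex$sweep_pre))
})

test_that("lambda sweep output shrinks the spectral radius as regularization grows", {
  ex <- get_smoke_experiment()
  p1 <- ex$checkpoints[[1]]
  set.seed(31)
  sw <- lambda_sweep(p1, ex$model, lambda_grid = c(0.05, 0.3, 2),
                     iters_2 = 2000L)
  expect_false(any(sw$failed))
  expect_true(all(diff(sw$rho_pre) < 0))
  expect_lt(sw$rho_pre[3], 0.2)  # strong decay dominates
})
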