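#' Preferred frequency of each output neuron
#'
#' The channel index maximizing each feed-forward row; ties break toward
#' the lowest channel. All-zero rows are flagged `NA` with a warning.
#'
#' @param W feed-forward matrix (N x M).
#' @return integer vector of channel indices, length N.
#' @export
preferred_frequency <- function(W) {
  W <- as.matrix(W)
  pf <- apply(W, 1, function(r) if (all(r == 0)) NA_integer_ else which.max(r))
  if (anyNA(pf)) warning(sum(is.na(pf)), " all-zero rows: preferred frequency undefined")
  as.integer(pf)
}

#' Aligned average row profile of a connectivity matrix
#'
#' Re-indexes the presynaptic connections of every postsynaptic neuron in
#' `subset` by the offset between presynaptic and postsynaptic preferred
#' frequency (on the log-scaled channel axis) and averages per offset bin.
#' The Mexican-hat signature is a positive value at zero offset with
#' negative flanks at intermediate offsets.
#'
#' @param K connectivity matrix (N x N); row i holds the incoming
#'   connections of neuron i.
#' @param pref preferred-frequency channel per neuron (length N).
#' @param subset postsynaptic neurons to average over (default all).
#' @return data frame with `offset`, `mean` and the contributing pair
#'   count `n`; autapses (diagonal) are excluded.
#' @export
aligned_row_profile <- function(K, pref, subset = seq_len(nrow(K))) {
  K <- as.matrix(K)
  N <- nrow(K)
  stopifnot(length(pref) == N, length(subset) >= 1)
  offs <- list()
  vals <- list()
  for (i in subset) {
    if (is.na(pref[i])) next
    j <- setdiff(seq_len(N), i)
    ok <- !is.na(pref[j])
    offs[[length(offs) + 1L]] <- pref[j][ok] - pref[i]
    vals[[length(vals) + 1L]] <- K[i, j][ok]
  }
  off <- unlist(offs)
  val <- unlist(vals)
  agg <- tapply(val, off, mean)
  cnt <- tapply(val, off, length)
  data.frame(offset = as.integer(names(agg)),
             mean = as.numeric(agg),
             n = as.integer(cnt),
             row.names = NULL)
}

#' Classify output neurons into deprived / non-deprived zones
#'
#' A neuron is deprived iff the attenuation profile value at its preferred
#' frequency falls below `cutoff`.
#'
#' @param pref preferred-frequency channel per neuron.
#' @param profile an `attenuation_profile`.
#' @param cutoff attenuation level separating the zones, in (0, 1).
#' @return list with `preferred_frequency` and factor `zone` (levels
#'   `deprived`, `non_deprived`; `NA` where the preferred frequency is
#'   undefined).
#' @export
classify_zones <- function(pref, profile, cutoff = 0.5) {
  stopifnot(inherits(profile, "attenuation_profile"),
            cutoff > 0, cutoff < 1)
  a <- profile$values[pref]
  zone <- ifelse(is.na(a), NA_character_,
                 ifelse(a < cutoff, "deprived", "non_deprived"))
  list(preferred_frequency = pref,
       zone = factor(zone, levels = c("deprived", "non_deprived")))
}

#' Score stimulus-independent (hallucination-like) activity
#'
#' Finds the silent-input attractor by Euler integration from the
#' homogeneous state `g(-theta)` perturbed by small uniform noise (the
#' homogeneous point is unstable in the supercritical regime, so a
#' noiseless start would be misleading), then scores the maximal excess of
#' the attractor over the spontaneous baseline recorded from the
#' pre-deprivation network.
#'
#' @param params a trained [network_params()].
#' @param baseline length-N spontaneous activity (the pre-deprivation
#'   silent response).
#' @param noise_mag magnitude of the uniform perturbation on the initial
#'   state.
#' @param threshold_sd the score is flagged as a hallucination when it
#'   exceeds `threshold_sd` times the across-neuron standard deviation of
#'   the baseline (reported raw so users can re-threshold).
#' @param threshold_floor absolute lower bound on the detection threshold,
#'   guarding against a spuriously sensitive flag when the baseline is
#'   (near-)homogeneous and its standard deviation is at solver precision.
#' @param dt,tol,max_steps Euler settings.
#' @return list with `score` (max over neurons of attractor minus
#'   baseline), `peak_neuron`, `peak_channel` (its preferred frequency),
#'   `popvec_magnitude`, `is_hallucinating`, `converged` and the attractor
#'   state `s`.
#' @export
hallucination_score <- function(params, baseline, noise_mag = 1e-3,
                                threshold_sd = 5, threshold_floor = 0.01,
                                dt = 0.1, tol = 1e-6, max_steps = 1e6) {
  stopifnot(length(baseline) == params$N)
  silent <- numeric(params$M)
  s0 <- stats::plogis(-params$theta) + stats::runif(params$N, 0, noise_mag)
  att <- integrate_euler(params, silent, s0 = s0, dt = dt, tol = tol,
                         max_steps = max_steps)
  excess <- att$s - baseline
  peak <- which.max(excess)
  pf <- preferred_frequency(params$W)
  thr <- max(threshold_sd * stats::sd(baseline), threshold_floor)
  list(score = max(excess),
       peak_neuron = peak,
       peak_channel = pf[peak],
       popvec_magnitude = population_vector_magnitude(att$s),
       is_hallucinating = att$converged && max(excess) > thr,
       converged = att$converged,
       s = att$s)
}

#' Simulated audiogram
#'
#' Per input channel, the probe amplitude required to shift the network's
#' steady-state response away from its silent baseline by `criterion` in
#' the infinity norm, found by bisection on `[interval[1], interval[2]]`
#' to amplitude tolerance `tol`. Channels whose criterion is unreachable
#' at the upper interval edge are flagged (`ceiling = TRUE`, threshold set
#' to the edge).
#'
#' @param params a trained [network_params()].
#' @param interval amplitude search interval (default \[0, 100\]).
#' @param tol bisection amplitude tolerance.
#' @param criterion required infinity-norm response difference.
#' @param probe_width `NULL` for a single-channel delta probe, else a
#'   Gaussian tone width in channel units.
#' @param attenuation optional `attenuation_profile` modelling the
#'   peripheral hearing loss; the probe is attenuated by it before reaching
#'   the network, which is what elevates the measured thresholds inside the
#'   attenuated band.
#' @param newton_tol steady-state solver tolerance.
#' @return data frame (class `audiogram`) with `channel`, `threshold`,
#'   `achieved_diff`, `ceiling`.
#' @export
simulate_audiogram <- function(params, interval = c(0, 100), tol = 1e-6,
                               criterion = 0.01, probe_width = NULL,
                               attenuation = NULL, newton_tol = 1e-12) {
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  silent <- steady_state_newton(params, numeric(params$M), tol = newton_tol)
  if (!silent$converged) stop("silent steady state did not converge")
  diff_at <- function(k, a) {
    x <- pure_tone_probe(k, a, params$M, width = probe_width)
    if (!is.null(attenuation)) x <- apply_attenuation(x, attenuation)
    st <- steady_state_newton(params, x, tol = newton_tol)
    if (!st$converged) return(NA_real_)
    max(abs(st$s - silent$s))
  }
  rows <- vector("list", params$M)
  for (k in seq_len(params$M)) {
    lo <- interval[1]
    hi <- interval[2]
    d_hi <- diff_at(k, hi)
    if (is.na(d_hi) || d_hi < criterion) {
      rows[[k]] <- data.frame(channel = k, threshold = hi,
                              achieved_diff = d_hi, ceiling = TRUE)
      next
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      d <- diff_at(k, mid)
      if (is.na(d)) break
      if (d < criterion) lo <- mid else hi <- mid
    }
    thr <- (lo + hi) / 2
    rows[[k]] <- data.frame(channel = k, threshold = thr,
                            achieved_diff = diff_at(k, thr),
                            ceiling = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("audiogram", class(out))
  out
}

#' Spectral radius versus recurrent regularization
#'
#' Re-runs the recurrent training phase (and, when `attenuation` is given,
#' the subsequent deprivation phase) from one shared feed-forward
#' checkpoint for every value of `lambda_grid`, recording the spectral
#' radius of K at each phase end. The hallucination interval is the lambda
#' range where the pre-deprivation network stays subcritical while the
#' post-deprivation network sits near the critical radius of 4.
#'
#' @param params_phase1 the shared phase-1 checkpoint (K = 0, trained W and
#'   theta).
#' @param model a calibrated [stimulus_model()].
#' @param lambda_grid recurrent regularization coefficients to test.
#' @param attenuation an `attenuation_profile`, or `NULL` to skip the
#'   deprivation phase.
#' @param iters_2,iters_3 per-phase sample counts.
#' @param eta learning rate for the recurrent phases.
#' @param rec_norm recurrent regularization norm.
#' @param rho_near_critical radius above which a network counts as
#'   near-critical when deriving the hallucination interval.
#' @return data frame with `lambda_K`, `rho_pre`, `rho_post` (NA rows mark
#'   failed runs); attribute `hallucination_interval` gives the lambda
#'   range (or NULL when empty / not derivable).
#' @export
lambda_sweep <- function(params_phase1, model, lambda_grid,
                         attenuation = NULL, iters_2 = 20000L,
                         iters_3 = 20000L, eta = 0.001, rec_norm = "l2",
                         rho_near_critical = 3.5) {
  rows <- vector("list", length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    lam <- lambda_grid[i]
    rho_pre <- NA_real_
    rho_post <- NA_real_
    ok <- tryCatch({
      cfg2 <- learning_config(eta = eta, lambda_K = lam, rec_norm = rec_norm,
                              n_iterations = iters_2, train_K = TRUE)
      res2 <- train_phase(params_phase1, cfg2,
                          function() generate_stimulus(model),
                          trace_every = 0L)
      rho_pre <- spectral_radius(res2$params$K)
      if (!is.null(attenuation)) {
        cfg3 <- learning_config(eta = eta, lambda_K = lam,
                                rec_norm = rec_norm,
                                n_iterations = iters_3, train_K = TRUE)
        res3 <- train_phase(res2$params, cfg3,
                            function() apply_attenuation(
                              generate_stimulus(model), attenuation),
                            trace_every = 0L)
        rho_post <- spectral_radius(res3$params$K)
      }
      TRUE
    }, error = function(e) FALSE)
    rows[[i]] <- data.frame(lambda_K = lam, rho_pre = rho_pre,
                            rho_post = rho_post, failed = !ok)
  }
  out <- do.call(rbind, rows)
  if (!is.null(attenuation)) {
    in_band <- !out$failed & !is.na(out$rho_pre) & !is.na(out$rho_post) &
      out$rho_pre < rho_near_critical & out$rho_post >= rho_near_critical
    attr(out, "hallucination_interval") <-
      if (any(in_band)) range(out$lambda_K[in_band]) else NULL
  }
  out
}

#' End-to-end sensory-deprivation experiment
#'
#' Runs the full pipeline at a configurable scale: stimulus calibration,
#' tonotopic initialization, the three-phase schedule, then the analysis
#' battery on the pre- and post-deprivation checkpoints (connectivity
#' profiles, zone classification, spontaneous baseline, hallucination
#' score, scaling sweeps over a shared evaluation set, and audiograms).
#' All randomness flows from the caller's RNG state; seed before calling
#' for reproducibility. When `out_dir` is given, the measure tables are
#' written there as tab-separated files and the checkpoints as RDS.
#'
#' @param M,N input and output dimensions.
#' @param attenuation an `attenuation_profile` for the deprivation phase
#'   (defaults to the high-frequency sigmoid at mid-band, steepness 10).
#' @param iters_1,iters_2,iters_3 per-phase sample counts.
#' @param lambda_W,lambda_K regularization coefficients. The sharp-drop
#'   location of rho(K) versus lambda_K depends mainly on N, so lambda_K
#'   must be re-chosen per network size by a coarse [lambda_sweep()]; the
#'   default 0.12 sits near the upper bound of the hallucination interval
#'   for the default M = 10, N = 40 configuration (for the full-size
#'   M = 40, N = 400 network use 0.226).
#' @param n_calibration stimulus-calibration batch size.
#' @param n_eval evaluation-set size for sweeps/correlations.
#' @param n_sigma number of points in the scaling grid.
#' @param sweep_max_steps Euler budget per sweep point.
#' @param audiogram whether to compute pre/post audiograms.
#' @param out_dir optional output directory for tables and checkpoints.
#' @return list with `model`, `checkpoints`, `traces`, `zones`,
#'   `profile_pre`, `profiles_post` (deprived / non-deprived),
#'   `baseline`, `hallucination`, `sweep_pre`, `sweep_post`,
#'   `critical_sigma_pre`, `critical_sigma_post`, and (optionally)
#'   `audiogram_pre`, `audiogram_post`.
#' @export
deprivation_experiment <- function(M = 10L, N = 40L,
                                   attenuation = NULL,
                                   iters_1 = 20000L, iters_2 = 30000L,
                                   iters_3 = 30000L,
                                   lambda_W = 0.001, lambda_K = 0.12,
                                   n_calibration = 5000L,
                                   n_eval = 200L, n_sigma = 25L,
                                   sweep_max_steps = 2e4,
                                   audiogram = TRUE,
                                   out_dir = NULL) {
  if (is.null(attenuation)) {
    attenuation <- sigmoid_attenuation(k0 = M / 2, beta = 10, M = M)
  }
  model <- calibrate_normalization(stimulus_model(n_channels = M),
                                   n_calibration = n_calibration)
  init <- init_feedforward_tonotopic(M, N)
  params0 <- network_params(init$W, theta = init$theta)
  phases <- default_schedule(attenuation, iters_1 = iters_1,
                             iters_2 = iters_2, iters_3 = iters_3,
                             lambda_K = lambda_K, lambda_W = lambda_W)
  fit <- run_schedule(params0, phases, model)
  pre <- fit$checkpoints[[2]]    # post recurrent pretraining
  post <- fit$checkpoints[[3]]   # post deprivation
  pf <- preferred_frequency(post$W)
  zones <- classify_zones(pf, attenuation)
  profile_pre <- aligned_row_profile(pre$K, preferred_frequency(pre$W))
  idx_dep <- which(zones$zone == "deprived")
  idx_non <- which(zones$zone == "non_deprived")
  profiles_post <- list(
    deprived = if (length(idx_dep)) aligned_row_profile(post$K, pf, idx_dep) else NULL,
    non_deprived = if (length(idx_non)) aligned_row_profile(post$K, pf, idx_non) else NULL)
  # spontaneous baseline: deterministic pre-deprivation silent response
  baseline_st <- steady_state_newton(pre, numeric(M), tol = 1e-12)
  baseline <- baseline_st$s
  hall_pre <- hallucination_score(pre, baseline, max_steps = sweep_max_steps * 10)
  hall_post <- hallucination_score(post, baseline, max_steps = sweep_max_steps * 10)
  eval_stimuli <- generate_stimulus(model, n_eval)
  sweep_pre <- scale_sweep(pre, eval_stimuli, sigma_grid = make_sigma_grid(pre, n_sigma),
                           max_steps = sweep_max_steps)
  sweep_post <- scale_sweep(post, eval_stimuli, sigma_grid = make_sigma_grid(post, n_sigma),
                            max_steps = sweep_max_steps)
  out <- list(model = model,
              checkpoints = fit$checkpoints,
              traces = fit$traces,
              attenuation = attenuation,
              zones = zones,
              profile_pre = profile_pre,
              profiles_post = profiles_post,
              baseline = baseline,
              hallucination_pre = hall_pre,
              hallucination = hall_post,
              sweep_pre = sweep_pre,
              sweep_post = sweep_post,
              critical_sigma_pre = attr(sweep_pre, "critical_sigma"),
              critical_sigma_post = attr(sweep_post, "critical_sigma"))
  if (audiogram) {
    out$audiogram_pre <- simulate_audiogram(pre)
    out$audiogram_post <- simulate_audiogram(post, attenuation = attenuation)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out$sweep_pre, file.path(out_dir, "sweep_pre.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(out$sweep_post, file.path(out_dir, "sweep_post.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (audiogram) {
      utils::write.table(out$audiogram_pre,
                         file.path(out_dir, "audiogram_pre.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(out$audiogram_post,
                         file.path(out_dir, "audiogram_post.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write_network(pre, file.path(out_dir, "checkpoint_pre.rds"),
                  meta = list(phase = 2))
    write_network(post, file.path(out_dir, "checkpoint_post.rds"),
                  meta = list(phase = 3))
  }
  out
}

# Default scaling grid: log-spaced up to 1.5x the critical scale.
make_sigma_grid <- function(params, n_sigma) {
  cs <- 4 / spectral_radius(params$K)
  exp(seq(log(0.05), log(1.5 * cs), length.out = n_sigma))
}
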