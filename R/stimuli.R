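#' Synthetic auditory stimulus model
#'
#' Describes the generative model for input vectors on a log-frequency axis
#' of `n_channels` input neurons. Each sample is a mixture of up to
#' `max_tones` Gaussian tones (centers uniform on the channel axis, widths
#' folded-normal, amplitudes uniform on `amp_range`) plus per-channel
#' additive uniform noise, globally rescaled so that all activations lie in
#' \[0, 0.5\]. The rescaling divisor (`norm_scale`) is fixed once by
#' [calibrate_normalization()] before any sample is emitted.
#'
#' @param n_channels number of input neurons M (log-spaced frequencies).
#' @param max_tones,min_tones bounds on the number of tones per sample; the
#'   count is drawn uniformly from `min_tones:max_tones`.
#' @param amp_range two positive reals, the uniform tone-amplitude range
#'   (arbitrary units).
#' @param width_scale standard deviation of the folded-normal tone widths,
#'   in channel units; defaults to half the input domain.
#' @param width_floor lower clamp on tone widths, avoiding degenerate
#'   single-channel spikes.
#' @param noise_range two reals, the per-channel additive uniform noise
#'   range.
#' @param norm_scale global divisor; `NULL` until calibrated.
#' @return an object of class `stimulus_model`.
#' @seealso [calibrate_normalization()], [generate_stimulus()]
#' @export
stimulus_model <- function(n_channels = 40L, max_tones = 5L, min_tones = 1L,
                           amp_range = c(7, 10),
                           width_scale = n_channels / 2,
                           width_floor = 0.25,
                           noise_range = c(0, 1),
                           norm_scale = NULL) {
  stopifnot(n_channels >= 2,
            min_tones >= 0, max_tones >= min_tones,
            length(amp_range) == 2, amp_range[1] <= amp_range[2],
            width_scale > 0, width_floor >= 0,
            length(noise_range) == 2, noise_range[1] <= noise_range[2],
            is.null(norm_scale) || norm_scale > 0)
  structure(list(n_channels = as.integer(n_channels),
                 max_tones = as.integer(max_tones),
                 min_tones = as.integer(min_tones),
                 amp_range = as.numeric(amp_range),
                 width_scale = width_scale,
                 width_floor = width_floor,
                 noise_range = as.numeric(noise_range),
                 norm_scale = norm_scale),
            class = "stimulus_model")
}

# One raw (un-normalized) sample: tone mixture plus additive noise.
raw_stimulus <- function(model) {
  M <- model$n_channels
  x <- stats::runif(M, model$noise_range[1], model$noise_range[2])
  n_tones <- if (model$max_tones > model$min_tones) {
    sample(model$min_tones:model$max_tones, 1L)
  } else {
    model$max_tones
  }
  if (n_tones > 0) {
    centers <- stats::runif(n_tones, 1, M)
    widths <- pmax(abs(stats::rnorm(n_tones, 0, model$width_scale)),
                   model$width_floor)
    amps <- stats::runif(n_tones, model$amp_range[1], model$amp_range[2])
    k <- seq_len(M)
    for (t in seq_len(n_tones)) {
      x <- x + amps[t] * exp(-(k - centers[t])^2 / (2 * widths[t]^2))
    }
  }
  x
}

#' Fix the global normalization scale of a stimulus model
#'
#' Draws `n_calibration` raw samples and sets `norm_scale` to twice the
#' highest activation observed over all samples and channels, so that
#' subsequently generated samples lie in \[0, 0.5\]. The scale is fixed once
#' and reused for the whole run; rare later samples exceeding the
#' calibration maximum are clipped to 0.5.
#'
#' @param model a [stimulus_model()].
#' @param n_calibration number of raw calibration samples (>= 1).
#' @return the model with `norm_scale` set.
#' @export
calibrate_normalization <- function(model, n_calibration = 10000L) {
  stopifnot(inherits(model, "stimulus_model"))
  if (n_calibration < 1) stop("n_calibration must be >= 1")
  peak <- 0
  for (i in seq_len(n_calibration)) {
    peak <- max(peak, max(raw_stimulus(model)))
  }
  model$norm_scale <- 2 * peak
  model
}

#' Generate normalized stimulus samples
#'
#' @param model a calibrated [stimulus_model()].
#' @param n number of samples.
#' @return for `n = 1` a length-M vector, otherwise an `n` x M matrix, with
#'   all entries in \[0, 0.5\].
#' @export
generate_stimulus <- function(model, n = 1L) {
  stopifnot(inherits(model, "stimulus_model"))
  if (is.null(model$norm_scale)) {
    stop("stimulus model is not calibrated; run calibrate_normalization() first")
  }
  out <- matrix(0, nrow = n, ncol = model$n_channels)
  for (i in seq_len(n)) {
    out[i, ] <- pmin(raw_stimulus(model) / model$norm_scale, 0.5)
  }
  if (n == 1L) drop(out) else out
}

new_attenuation <- function(values, params) {
  stopifnot(all(values >= 0), all(values <= 1))
  structure(list(values = as.numeric(values), params = params),
            class = "attenuation_profile")
}

#' Sigmoidal attenuation profile
#'
#' Multiplicative per-channel envelope `a(k) = 1 / (1 + exp(-beta (k0 - k)))`
#' over channels `k = 1..M`. Positive `beta` attenuates high frequencies
#' (channels above `k0`); negative `beta` gives the non-inverted sigmoid
#' attenuating low frequencies.
#'
#' @param k0 transition channel (in the 1-based input-neuron domain).
#' @param beta steepness; sign selects which side is attenuated.
#' @param M number of channels.
#' @return an `attenuation_profile`.
#' @export
sigmoid_attenuation <- function(k0, beta, M) {
  stopifnot(M >= 2)
  k <- seq_len(M)
  new_attenuation(stats::plogis(beta * (k0 - k)),
                  list(k0 = k0, beta = beta))
}

#' Band attenuation profile
#'
#' Combines two sigmoids to attenuate the band `[k1, k2]`:
#' `a(k) = 1 - (1 - 1/(1+exp(-beta (k1 - k)))) * (1 - 1/(1+exp(-beta (k - k2))))`.
#'
#' @param k1,k2 band edges in channel units, `k1 < k2`.
#' @param beta steepness of both edges.
#' @param M number of channels.
#' @return an `attenuation_profile`.
#' @export
band_attenuation <- function(k1, k2, beta, M) {
  stopifnot(M >= 2)
  if (k1 >= k2) stop("band edges must satisfy k1 < k2")
  k <- seq_len(M)
  v <- 1 - (1 - stats::plogis(beta * (k1 - k))) * (1 - stats::plogis(beta * (k - k2)))
  new_attenuation(v, list(k1 = k1, k2 = k2, beta = beta))
}

#' Apply an attenuation profile to a stimulus
#'
#' @param x input vector.
#' @param profile an `attenuation_profile` of matching length.
#' @return the elementwise product.
#' @export
apply_attenuation <- function(x, profile) {
  stopifnot(inherits(profile, "attenuation_profile"))
  if (length(x) != length(profile$values)) {
    stop("stimulus length does not match attenuation profile length")
  }
  x * profile$values
}

#' Single-frequency probe stimulus
#'
#' Input vector in which only one frequency channel is active, used for
#' simulated audiograms. By default a delta probe (a single nonzero
#' channel); a narrow Gaussian tone is available via `width`.
#'
#' @param k active channel index (1-based).
#' @param amplitude probe amplitude (>= 0).
#' @param M number of channels.
#' @param width `NULL` for a delta probe, otherwise the Gaussian tone width
#'   in channel units.
#' @return a length-M vector.
#' @export
pure_tone_probe <- function(k, amplitude, M, width = NULL) {
  if (k < 1 || k > M) stop("probe channel out of range")
  stopifnot(amplitude >= 0)
  if (is.null(width)) {
    x <- numeric(M)
    x[k] <- amplitude
  } else {
    stopifnot(width > 0)
    x <- amplitude * exp(-(seq_len(M) - k)^2 / (2 * width^2))
  }
  x
}
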