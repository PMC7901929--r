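#' Synthetic cardiorespiratory epoch
#'
#' Generates one paired (respiration, HRV) epoch with known ground truth,
#' emulating the structure of polysomnography-derived 5-min segments:
#' respiration is either a narrow-band oscillation around a breathing
#' frequency (5% frequency jitter, 5% additive white noise) or -- mimicking
#' apneic breathing -- 0.1--0.6 Hz band-limited Gaussian noise; the HRV is a
#' controllable mixture of a linear and a quadratic (mean-removed) function
#' of lag-1 respiration, a low-frequency 0.04--0.15 Hz noise component
#' standing in for non-respiratory autonomic modulation, and 5% white noise.
#' Both channels pass through the standard band-pass ([bandpass()]).
#'
#' @param resp_mode `"narrowband"` or `"broadband"`.
#' @param resp_freq Breathing frequency in Hz (narrowband mode; in (0.1, 0.5)).
#' @param gain_linear Linear respiratory drive gain (>= 0).
#' @param gain_quadratic Quadratic drive gain (>= 0).
#' @param noise_lf Amplitude of the 0.04--0.15 Hz HRV noise (>= 0).
#' @param n_samples Epoch length in samples (default 600 = 5 min at 2 Hz).
#' @param fs Sampling rate (default 2 Hz).
#' @param seed Integer seed (deterministic per seed).
#' @return An [rsa_epoch()] whose attribute `"ground_truth"` records the two
#'   gains and the generator settings.
#' @export
#'
#' @examples
#' ep <- generate_epoch(gain_linear = 1, gain_quadratic = 0, seed = 1)
#' ep
generate_epoch <- function(resp_mode = c("narrowband", "broadband"),
                           resp_freq = 0.25, gain_linear = 1,
                           gain_quadratic = 0, noise_lf = 0.3,
                           n_samples = 600L, fs = 2, seed = NULL) {
  resp_mode <- match.arg(resp_mode)
  if (resp_mode == "narrowband" && (resp_freq <= 0.1 || resp_freq >= 0.5)) {
    stop("'resp_freq' must lie in (0.1, 0.5) Hz for narrowband respiration")
  }
  if (gain_linear < 0 || gain_quadratic < 0 || noise_lf < 0) {
    stop("gains and noise amplitudes must be non-negative")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 128L) stop("'n_samples' too small for an epoch")
  sig <- with_seed(seed, {
    resp <- if (resp_mode == "narrowband") {
      # slowly wandering instantaneous frequency (5% sd) + 5% white noise
      drift <- bandlimited_noise(n_samples, fs, 0.01, 0.05)
      f_inst <- resp_freq * (1 + 0.05 * drift)
      s <- sin(2 * pi * cumsum(f_inst) / fs)
      s + 0.05 * stats::sd(s) * stats::rnorm(n_samples) / 1
    } else {
      bandlimited_noise(n_samples, fs, 0.1, 0.6)
    }
    resp <- resp / stats::sd(resp)
    lag1 <- c(0, resp[-n_samples])
    quad <- lag1^2 - mean(lag1^2)
    hrv <- gain_linear * lag1 + gain_quadratic * quad +
      noise_lf * bandlimited_noise(n_samples, fs, 0.04, 0.15) +
      0.05 * stats::rnorm(n_samples)
    list(resp = resp, hrv = hrv)
  })
  resp_f <- bandpass(uniform_signal(sig$resp, fs, "resp"))
  hrv_f <- bandpass(uniform_signal(sig$hrv, fs, "hrv"))
  ep <- rsa_epoch(resp_f, hrv_f)
  attr(ep, "ground_truth") <- list(resp_mode = resp_mode, resp_freq = resp_freq,
                                   gain_linear = gain_linear,
                                   gain_quadratic = gain_quadratic,
                                   noise_lf = noise_lf, seed = seed)
  ep
}

# Unit-variance Gaussian noise band-limited to [low, high] Hz
# (4th-order Butterworth, forward-backward).
bandlimited_noise <- function(n, fs, low, high) {
  w <- stats::rnorm(n)
  flt <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  v <- filtfilt_padded(flt, w, pad = ceiling(4.5 * fs / low))
  v / stats::sd(v)
}

#' Fixture grid of synthetic epochs
#'
#' Convenience generator for test/benchmark grids: a set of epochs sweeping
#' the linear gain at fixed quadratic gain (and vice versa), with the ground
#' truth attached to each epoch.
#'
#' @param gains_linear,gains_quadratic Numeric vectors of gains to cross.
#' @param n_seeds Epochs per gain combination.
#' @param base_seed Integer seed from which epoch seeds are derived.
#' @param ... Further arguments passed to [generate_epoch()].
#' @return A list of epochs; each has attributes `"ground_truth"`.
#' @export
generate_epoch_grid <- function(gains_linear = c(0, 0.5, 1, 2),
                                gains_quadratic = 0, n_seeds = 20L,
                                base_seed = 1L, ...) {
  combos <- expand.grid(gl = gains_linear, gq = gains_quadratic,
                        seed_idx = seq_len(n_seeds))
  lapply(seq_len(nrow(combos)), function(i) {
    generate_epoch(gain_linear = combos$gl[i], gain_quadratic = combos$gq[i],
                   seed = cell_seed(base_seed, i, combos$seed_idx[i]), ...)
  })
}
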