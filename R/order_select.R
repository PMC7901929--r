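#' Spectral model-order selection
#'
#' Chooses the autoregressive order L (number of past respiration samples)
#' from the respiration spectrum. A representative respiratory frequency Fr
#' is found as follows: (i) the frequency band holding 90% of the total
#' spectral mass is identified (5th to 95th percentile of the cumulative
#' mass); (ii) strict local maxima of the PSD inside that band are located;
#' (iii) with fewer than 3 maxima, Fr is the frequency of maximum power in
#' the band, otherwise the lowest-frequency local maximum; (iv) Fr is clamped
#' below by 0.1 Hz. L is then the number of samples covering two periods of
#' Fr: `L = ceiling(2 * fs / Fr)` (40 at most for 2 Hz signals).
#'
#' @param resp_psd An `rsa_psd` (see [welch_psd()]) of the respiration.
#' @param fs Sampling rate of the time-domain signal the order applies to (Hz).
#' @return List of class `rsa_order`: `Fr` (Hz), `L`, `band` (c(f_low,
#'   f_high)), `n_maxima` (local maxima found in the band), `clamped`.
#' @export
#'
#' @examples
#' s <- uniform_signal(sin(2 * pi * 0.25 * (0:599) / 2), fs = 2)
#' select_order(welch_psd(s), fs = 2)
select_order <- function(resp_psd, fs) {
  stopifnot(inherits(resp_psd, "rsa_psd"))
  f <- resp_psd$freqs
  p <- resp_psd$power
  if (length(f) < 8L) stop("PSD too coarse for order selection (need >= 8 bins)")
  if (any(p < 0) || sum(p) <= 0) stop("PSD must be non-negative with positive total power")
  cum <- cumsum(p) / sum(p)
  i_lo <- which(cum >= 0.05)[1L]
  i_hi <- which(cum >= 0.95)[1L]
  band_idx <- i_lo:i_hi
  maxima <- intersect(local_maxima(p), band_idx)
  n_max <- length(maxima)
  if (n_max < 3L) {
    Fr <- f[band_idx][which.max(p[band_idx])]
  } else {
    Fr <- f[min(maxima)]
  }
  clamped <- Fr < 0.1
  if (clamped) Fr <- 0.1
  L <- as.integer(ceiling(2 * fs / Fr))
  structure(list(Fr = Fr, L = L, band = c(f[i_lo], f[i_hi]),
                 n_maxima = n_max, clamped = clamped),
            class = "rsa_order")
}

#' @export
print.rsa_order <- function(x, ...) {
  cat(sprintf("<rsa_order> Fr = %.3f Hz%s, band [%.3f, %.3f] Hz, %d maxima -> L = %d\n",
              x$Fr, if (x$clamped) " (clamped)" else "", x$band[1L], x$band[2L],
              x$n_maxima, x$L))
  invisible(x)
}

# Strict local maxima of a vector: greater than both flanking values, with
# plateaus represented by their leftmost index.
local_maxima <- function(p) {
  n <- length(p)
  out <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && p[j + 1L] == p[i]) j <- j + 1L
    left <- if (i > 1L) p[i - 1L] else -Inf
    right <- if (j < n) p[j + 1L] else -Inf
    if (p[i] > left && p[i] > right) out <- c(out, i)
    i <- j + 1L
  }
  out
}

# Resolve an order policy ("auto" or a fixed integer) for a respiration signal.
resolve_order <- function(resp, order = "auto", window_s = 40, overlap_s = 20) {
  if (identical(order, "auto")) {
    n <- length(resp$samples)
    ws <- min(window_s, n / resp$fs)  # never ask for a window longer than the data
    select_order(welch_psd(resp, window_s = ws, overlap_s = min(overlap_s, ws / 2)),
                 fs = resp$fs)$L
  } else {
    L <- as.integer(order)
    if (is.na(L) || L < 1L) stop("'order' must be \"auto\" or a positive integer")
    L
  }
}
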