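#' Interpolated RR tachogram from R-peak times
#'
#' Converts a series of R-peak occurrence times into the HRV representation
#' used throughout the package: the RR interval series, placed at the time of
#' each interval's closing peak and cubic-spline interpolated onto a uniform
#' grid (2 Hz by default).
#'
#' @param peak_times Strictly increasing numeric vector of R-peak times (s).
#' @param fs_out Output sampling frequency in Hz (default 2).
#' @return A `uniform_signal` of RR intervals (seconds) at `fs_out`. The
#'   attribute `"flagged"` is `TRUE` when any RR interval falls outside the
#'   physiological range (0.2, 4.0) s.
#' @export
#'
#' @examples
#' tach <- tachogram_from_rpeaks(seq(0, 100, by = 1))  # 60 bpm -> constant 1 s
#' range(tach$samples)
tachogram_from_rpeaks <- function(peak_times, fs_out = 2) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) < 3L) stop("need at least 3 R-peaks")
  if (any(!is.finite(peak_times))) stop("non-finite peak times")
  rr <- diff(peak_times)
  if (any(rr <= 0)) stop("peak times must be strictly increasing")
  flagged <- any(rr <= 0.2 | rr >= 4.0)
  t_rr <- peak_times[-1L]  # closing peak of each interval
  grid <- seq(t_rr[1L], t_rr[length(t_rr)], by = 1 / fs_out)
  f <- stats::splinefun(t_rr, rr, method = "natural")
  out <- uniform_signal(f(grid), fs = fs_out, label = "hrv")
  attr(out, "flagged") <- flagged
  attr(out, "t0") <- grid[1L]
  out
}

#' Zero-phase Butterworth band-pass
#'
#' Applies a 4th-order Butterworth band-pass (0.03--1 Hz by default) in
#' forward and backward directions, as is standard for HRV/respiration
#' conditioning. When the upper edge reaches the Nyquist frequency -- as it
#' does for the default band at 2 Hz, where no energy above 1 Hz can exist --
#' the filter degrades gracefully to the high-pass half alone, with a message.
#'
#' @param x A `uniform_signal` (or numeric vector with `fs`).
#' @param low,high Band edges in Hz.
#' @param order Butterworth order (applied twice via `filtfilt`).
#' @param fs Sampling rate, only used when `x` is a bare vector.
#' @return Filtered `uniform_signal`, same length as the input.
#' @export
bandpass <- function(x, low = 0.03, high = 1.0, order = 4, fs = NULL) {
  x <- as_uniform_signal(x, fs)
  nyq <- x$fs / 2
  if (low <= 0 || low >= nyq) stop("'low' must lie in (0, fs/2)")
  n <- length(x$samples)
  if (n <= 9 * order) stop("signal too short for stable zero-phase filtering")
  if (high >= 0.95 * nyq) {
    message(sprintf(
      "bandpass: upper edge %.3g Hz is at/above 0.95*Nyquist (fs = %g Hz); using %d-th order high-pass at %.3g Hz only",
      high, x$fs, order, low))
    flt <- signal::butter(order, low / nyq, type = "high")
  } else {
    if (high <= low) stop("'high' must exceed 'low'")
    flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  }
  y <- filtfilt_padded(flt, x$samples, pad = ceiling(4.5 * x$fs / low))
  uniform_signal(y, fs = x$fs, label = x$label)
}

# Zero-phase (forward-backward) filtering with transient suppression. A
# low cut-off filter rings over ~fs/fc samples, and any kink at the joint
# between the data and its extension lands exactly at the retained
# boundary, so the ends must be continued smoothly: (i) the straight line
# through the two endpoints is removed -- it lies in the stop band of every
# filter used here, so it is not restored; (ii) each end of the residual is
# extrapolated with a Burg autoregressive model (which continues
# oscillations in phase), tapered to zero across the pad; (iii) a further
# zero pad lets the turn-on transients of the forward and backward passes
# die out before the retained segment. The construction is symmetric under
# time reversal.
filtfilt_padded <- function(flt, x, pad) {
  n <- length(x)
  p <- min(n - 1L, as.integer(pad))
  line <- x[1L] + (x[n] - x[1L]) * (seq_len(n) - 1) / (n - 1)
  r <- x - line
  ext <- c(numeric(p), rev(ar_extend(rev(r), p)), r, ar_extend(r, p), numeric(p))
  y <- signal::filter(flt, ext)
  y <- rev(signal::filter(flt, rev(y)))
  y[(2L * p + 1L):(2L * p + n)]
}

# Deterministic AR continuation of a series: fit a Burg AR model (stable by
# construction) and iterate the recursion p steps past the end, tapering
# smoothly to zero. Falls back to zeros for degenerate or exploding fits.
ar_extend <- function(v, p) {
  n <- length(v)
  ord <- min(20L, n %/% 3L)
  ext <- tryCatch({
    if (ord < 1L || stats::var(v) == 0) {
      numeric(p)
    } else {
      a <- stats::ar(v, aic = FALSE, order.max = ord, method = "burg",
                     demean = FALSE)$ar
      la <- length(a)
      if (la == 0L) {
        numeric(p)
      } else {
        buf <- c(v[(n - la + 1L):n], numeric(p))
        for (k in seq_len(p)) {
          buf[la + k] <- sum(a * buf[(la + k - 1L):k])
        }
        buf[(la + 1L):(la + p)]
      }
    }
  }, error = function(e) numeric(p))
  if (!all(is.finite(ext)) || max(abs(ext)) > 5 * max(abs(v))) ext <- numeric(p)
  ext * 0.5 * (1 + cos(pi * seq_len(p) / p))
}

#' Anti-aliased resampling to a lower rate
#'
#' Applies an 8th-order Butterworth low-pass at 0.8 x (fs_out / 2)
#' (forward-backward) and linearly interpolates onto the new uniform grid.
#' Used to bring raw respiration channels to the 2 Hz analysis rate.
#'
#' @param x A `uniform_signal`.
#' @param fs_out Target sampling frequency (Hz), below `x$fs`.
#' @return Resampled `uniform_signal` at `fs_out`.
#' @export
resample_signal <- function(x, fs_out = 2) {
  stopifnot(inherits(x, "uniform_signal"))
  if (fs_out >= x$fs) stop("'fs_out' must be below the input rate")
  cutoff <- 0.8 * (fs_out / 2)
  flt <- signal::butter(8, cutoff / (x$fs / 2), type = "low")
  y <- filtfilt_padded(flt, x$samples, pad = ceiling(4.5 * x$fs / cutoff))
  t_in <- (seq_along(y) - 1) / x$fs
  t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
  uniform_signal(stats::approx(t_in, y, xout = t_out)$y, fs = fs_out, label = x$label)
}

#' Segment paired channels into fixed epochs
#'
#' Cuts a paired respiration/HRV record into consecutive non-overlapping
#' epochs (5 min by default); a trailing remainder shorter than one epoch is
#' dropped.
#'
#' @param resp,hrv `uniform_signal` objects with equal `fs` and length.
#' @param epoch_s Epoch length in seconds (default 300).
#' @return A list of [rsa_epoch()] objects (possibly empty).
#' @export
segment_epochs <- function(resp, hrv, epoch_s = 300) {
  stopifnot(inherits(resp, "uniform_signal"), inherits(hrv, "uniform_signal"))
  if (resp$fs != hrv$fs) stop("channels must share a sampling rate")
  n <- length(resp$samples)
  if (n != length(hrv$samples)) stop("channels must have equal length")
  len <- round(epoch_s * resp$fs)
  n_ep <- n %/% len
  if (n_ep == 0L) return(list())
  lapply(seq_len(n_ep), function(k) {
    idx <- ((k - 1L) * len + 1L):(k * len)
    rsa_epoch(
      uniform_signal(resp$samples[idx], resp$fs, resp$label),
      uniform_signal(hrv$samples[idx], hrv$fs, hrv$label),
      start_time = (k - 1L) * len / resp$fs
    )
  })
}

#' Welch power spectral density
#'
#' Averaged-periodogram PSD over Hamming-tapered overlapping segments
#' (40 s windows with 20 s overlap by default, matching the respiration
#' spectra used for model-order selection). One-sided density in
#' units^2 / Hz; no detrending, so a DC offset shows up in the 0 Hz bin.
#'
#' @param x A `uniform_signal` (or numeric vector with `fs`).
#' @param window_s Segment length in seconds.
#' @param overlap_s Segment overlap in seconds.
#' @param fs Sampling rate when `x` is a bare vector.
#' @return An object of class `rsa_psd`: list with `freqs` (Hz), `power`
#'   (density), and `total_power` (trapezoidal integral of the density).
#' @export
welch_psd <- function(x, window_s = 40, overlap_s = 20, fs = NULL) {
  x <- as_uniform_signal(x, fs)
  nwin <- round(window_s * x$fs)
  nov <- round(overlap_s * x$fs)
  if (nov >= nwin) stop("'overlap_s' must be smaller than 'window_s'")
  n <- length(x$samples)
  if (n < nwin) stop("signal shorter than one Welch window")
  hop <- nwin - nov
  starts <- seq(1L, n - nwin + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nwin - 1L)) / (nwin - 1L))  # Hamming
  scale <- x$fs * sum(w^2)
  nfreq <- nwin %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x$samples[s:(s + nwin - 1L)] * w
    sp <- (Mod(stats::fft(seg))^2 / scale)[seq_len(nfreq)]
    acc <- acc + sp
  }
  p <- acc / length(starts)
  # fold the negative-frequency half into interior bins (one-sided density)
  interior <- 2:(nfreq - 1L)
  if (nwin %% 2L == 0L) p[interior] <- 2 * p[interior]
  else p[2:nfreq] <- 2 * p[2:nfreq]
  freqs <- (seq_len(nfreq) - 1L) * x$fs / nwin
  total <- trapz(freqs, p)
  structure(list(freqs = freqs, power = p, total_power = total),
            class = "rsa_psd")
}

#' @export
print.rsa_psd <- function(x, ...) {
  cat(sprintf("<rsa_psd> %d bins, %.4g-%.4g Hz, total power %.4g\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$total_power))
  invisible(x)
}

# trapezoidal integral; x strictly increasing
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Read a two-column time/value CSV as a uniform signal
#'
#' Expects columns `time_s,value` with a header row; the time column must be
#' uniformly spaced (tolerance 1e-6 of the step).
#'
#' @param path CSV file path.
#' @param label Channel label.
#' @return A `uniform_signal`.
#' @export
read_signal_csv <- function(path, label = "") {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("expected two columns: time_s,value")
  tt <- as.numeric(df[[1L]]); v <- as.numeric(df[[2L]])
  dt <- diff(tt)
  if (any(abs(dt - dt[1L]) > 1e-6 * abs(dt[1L]))) {
    stop("time column is not uniformly spaced")
  }
  uniform_signal(v, fs = 1 / dt[1L], label = label)
}

#' Write a uniform signal as a two-column CSV
#' @param x A `uniform_signal`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "uniform_signal"))
  df <- data.frame(time_s = (seq_along(x$samples) - 1) / x$fs, value = x$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
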