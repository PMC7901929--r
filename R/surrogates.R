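#' Multivariate amplitude-adjusted surrogate pair
#'
#' Generates one surrogate realization of a paired (respiration, HRV) segment
#' under the null hypothesis of a purely linear, possibly cross-correlated
#' Gaussian process. A single conjugate-symmetric random phase vector (DC and
#' Nyquist untouched) is added to the Fourier phases of BOTH channels --
#' sharing the increment preserves the cross-spectrum, hence the
#' cross-correlation -- followed by joint iterative amplitude adjustment
#' (multivariate IAAFT): rank-order amplitude steps make each surrogate's
#' sorted values equal the original channel's sorted values exactly, and
#' every spectrum-restoration step reimposes the original amplitudes and
#' relative phases with one common per-frequency increment, so the
#' autocorrelations and the cross-correlation survive while any nonlinear
#' dependence between the channels is destroyed.
#'
#' @param x,y Numeric vectors of equal length (>= 64).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param max_iter Cap on IAAFT iterations (default 100); iteration also
#'   stops at rank convergence.
#' @return List with surrogate vectors `x` and `y` and the per-channel
#'   iteration counts `iters`.
#' @export
surrogate_pair <- function(x, y, seed = NULL, max_iter = 100L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("'x' and 'y' must have equal length")
  if (n < 64L) stop("segments shorter than 64 samples: spectral estimates unreliable")
  phi <- with_seed(seed, random_phase_increment(n))
  iaaft_pair(list(x, y), phi, max_iter)
}

# Conjugate-symmetric random phase increment of length n; zero at DC (and
# Nyquist for even n) so the surrogate stays real with the original mean.
random_phase_increment <- function(n) {
  phi <- numeric(n)
  n_half <- (n - 1L) %/% 2L
  if (n_half > 0L) {
    u <- stats::runif(n_half, 0, 2 * pi)
    phi[2L:(n_half + 1L)] <- u
    phi[n:(n - n_half + 1L)] <- -u
  }
  phi
}

# Joint multivariate IAAFT. Every spectrum-restoration step rewrites each
# channel's Fourier coefficients as (original amplitude) *
# exp(i * (original phase + phi)), with a SINGLE per-frequency increment phi
# shared by all channels, chosen as the amplitude-weighted circular mean of
# the channels' current phase offsets from the original. Keeping the
# increment common preserves the cross-spectrum (hence cross-correlation)
# exactly at every spectrum step, while the per-channel rank-order amplitude
# step enforces the exact sample multiset. DC (and Nyquist for even n) stay
# unrotated so the surrogate remains real with the original mean.
iaaft_pair <- function(channels, phi, max_iter) {
  n <- length(channels[[1L]])
  fv <- lapply(channels, stats::fft)
  amp <- lapply(fv, Mod)
  theta <- lapply(fv, Arg)
  sorted_v <- lapply(channels, sort)
  nch <- length(channels)
  fixed <- c(1L, if (n %% 2L == 0L) n %/% 2L + 1L)  # DC (+ Nyquist) bins
  rebuild <- function(phi) {
    lapply(seq_len(nch), function(k) {
      Re(stats::fft(amp[[k]] * exp(1i * (theta[[k]] + phi)), inverse = TRUE)) / n
    })
  }
  s <- rebuild(phi)
  prev_rank <- NULL
  iters <- 0L
  repeat {
    iters <- iters + 1L
    # exact amplitude multiset per channel
    rk <- lapply(s, rank, ties.method = "first")
    s <- lapply(seq_len(nch), function(k) sorted_v[[k]][rk[[k]]])
    if (identical(rk, prev_rank) || iters >= max_iter) break
    prev_rank <- rk
    # common phase increment closest to the current iterate
    z <- Reduce(`+`, lapply(seq_len(nch), function(k) {
      amp[[k]] * exp(1i * (Arg(stats::fft(s[[k]])) - theta[[k]]))
    }))
    phi <- Arg(z)
    phi[fixed] <- 0
    phi[!is.finite(phi)] <- 0
    s <- rebuild(phi)
  }
  list(x = s[[1L]], y = s[[2L]], iters = iters)
}

#' Surrogate-data significance test for nonlinear coupling
#'
#' Recomputes the RBF explained-variance index Pxk on surrogate pairs that
#' share the original channels' amplitude distributions, autocorrelations and
#' cross-correlation but carry no nonlinear dependence. The model order L of
#' the original epoch is reused; the bandwidth, regularization and tube width
#' are re-tuned per surrogate so every surrogate traverses the identical
#' pipeline. Nonlinearity is declared when the original Pxk exceeds the
#' empirical 95th quantile of the surrogate Pxk values.
#'
#' @param resp,hrv `uniform_signal`s or numeric vectors (one epoch).
#' @param order Order policy as in [coupling_indices()] (resolved once, on
#'   the original respiration).
#' @param n_surrogates Number of surrogate pairs (default 24).
#' @param seed Integer seed controlling all surrogate draws.
#' @param fs Sampling rate for bare vectors.
#' @param coupling Optional precomputed `rsa_coupling` for the original pair
#'   (avoids refitting when already available).
#' @return Object of class `rsa_surrogate_verdict`: `pxk_original`,
#'   `pxk_surrogates`, `threshold` (95th quantile), `significant`,
#'   `n_failed`.
#' @export
nonlinearity_test <- function(resp, hrv, order = "auto", n_surrogates = 24L,
                              seed = NULL, fs = 2, coupling = NULL) {
  n_surrogates <- as.integer(n_surrogates)
  if (is.na(n_surrogates) || n_surrogates < 1L) {
    stop("'n_surrogates' must be a positive integer")
  }
  resp <- as_uniform_signal(resp, fs, "resp")
  hrv <- as_uniform_signal(hrv, resp$fs, "hrv")
  if (is.null(coupling)) {
    coupling <- coupling_indices(resp, hrv, order = order, fs = resp$fs)
  }
  L <- coupling$L
  seeds <- surrogate_seeds(seed, n_surrogates)
  pxk_s <- rep(NA_real_, n_surrogates)
  for (i in seq_len(n_surrogates)) {
    pxk_s[i] <- tryCatch({
      sp <- surrogate_pair(resp$samples, hrv$samples, seed = seeds[i])
      pxk_index(sp$x, sp$y, L = L)
    }, error = function(e) {
      warning(sprintf("surrogate %d failed: %s", i, conditionMessage(e)),
              call. = FALSE)
      NA_real_
    })
  }
  ok <- pxk_s[is.finite(pxk_s)]
  need <- max(2L, ceiling(n_surrogates * 20 / 24))
  if (length(ok) < need) {
    stop(sprintf("only %d/%d surrogates succeeded (need >= %d)",
                 length(ok), n_surrogates, need))
  }
  thr <- as.numeric(stats::quantile(ok, 0.95, type = 7))
  structure(list(pxk_original = coupling$Pxk, pxk_surrogates = pxk_s,
                 threshold = thr, significant = coupling$Pxk > thr,
                 n_failed = n_surrogates - length(ok), L = L),
            class = "rsa_surrogate_verdict")
}

# Independent per-surrogate seeds derived from one user seed (kept < 2^31).
surrogate_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @export
print.rsa_surrogate_verdict <- function(x, ...) {
  cat(sprintf("<rsa_surrogate_verdict> Pxk = %.3f vs 95th surrogate quantile %.3f -> %s (%d surrogates%s)\n",
              x$pxk_original, x$threshold,
              if (x$significant) "nonlinear coupling" else "not significant",
              length(x$pxk_surrogates),
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}
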