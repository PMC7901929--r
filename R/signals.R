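#' Uniformly sampled signal
#'
#' Lightweight container for a real-valued, uniformly sampled time series:
#' the carrier for respiration, the interpolated tachogram (HRV), and
#' simulated series throughout the package.
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param label Optional free-text channel label.
#'
#' @return An object of class `uniform_signal`: a list with elements
#'   `samples`, `fs` and `label`.
#' @export
#'
#' @examples
#' s <- uniform_signal(sin(2 * pi * 0.25 * (0:599) / 2), fs = 2, label = "resp")
#' duration(s)
uniform_signal <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("'samples' must be non-empty")
  }
  if (!all(is.finite(samples))) {
    stop("'samples' must be finite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a positive scalar (Hz)")
  }
  structure(list(samples = samples, fs = as.numeric(fs), label = as.character(label)[1L]),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %s: %d samples @ %g Hz (%.1f s)\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              length(x$samples), x$fs, duration(x)))
  invisible(x)
}

#' Signal duration in seconds
#' @param x A `uniform_signal`.
#' @return Duration in seconds (n / fs).
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  length(x$samples) / x$fs
}

as_uniform_signal <- function(x, fs = NULL, label = "") {
  if (inherits(x, "uniform_signal")) return(x)
  if (is.null(fs)) stop("'fs' required when passing a bare numeric vector")
  uniform_signal(x, fs = fs, label = label)
}

#' Paired respiration/HRV epoch
#'
#' A fixed-length analysis segment holding a respiration channel and an HRV
#' channel sampled on the same grid (default 5 min at 2 Hz, i.e. 600 samples).
#'
#' @param resp,hrv `uniform_signal` objects with identical `fs` and length.
#' @param start_time Epoch start time in seconds within the parent record.
#' @param quality_flags Character vector of quality annotations.
#' @return An object of class `rsa_epoch`.
#' @export
rsa_epoch <- function(resp, hrv, start_time = 0, quality_flags = character()) {
  stopifnot(inherits(resp, "uniform_signal"), inherits(hrv, "uniform_signal"))
  if (resp$fs != hrv$fs) stop("epoch channels must share a sampling rate")
  if (length(resp$samples) != length(hrv$samples)) {
    stop("epoch channels must have equal length")
  }
  structure(list(resp = resp, hrv = hrv, start_time = as.numeric(start_time),
                 quality_flags = as.character(quality_flags)),
            class = "rsa_epoch")
}

#' @export
print.rsa_epoch <- function(x, ...) {
  cat(sprintf("<rsa_epoch> start %.1f s, %d samples @ %g Hz%s\n",
              x$start_time, length(x$resp$samples), x$resp$fs,
              if (length(x$quality_flags))
                paste0(" [", paste(x$quality_flags, collapse = ","), "]") else ""))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}
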