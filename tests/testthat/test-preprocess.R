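test_that("tachogram interpolation reproduces simple RR structures", {
  tach <- tachogram_from_rpeaks(seq(0, 100, by = 1), fs_out = 2)
  expect_equal(tach$fs, 2)
  expect_true(all(abs(tach$samples - 1.0) < 1e-6))

  # alternating 0.9/1.1 s intervals: oracle = direct mean of the sequence
  peaks <- cumsum(c(0, rep(c(0.9, 1.1), 50)))
  tach2 <- tachogram_from_rpeaks(peaks, fs_out = 2)
  expect_lt(abs(mean(tach2$samples) - 1.0), 1e-3)

  expect_error(tachogram_from_rpeaks(c(0, 1)), "at least 3")
  expect_error(tachogram_from_rpeaks(c(0, 2, 1)), "increasing")
  expect_true(attr(tachogram_from_rpeaks(c(0, 0.1, 1, 2)), "flagged"))
  expect_false(attr(tachogram_from_rpeaks(c(0, 1, 2, 3)), "flagged"))
})

test_that("band-pass is zero-phase, kills DC and attenuates sub-band drift", {
  t <- (0:599) / 2
  s <- uniform_signal(sin(2 * pi * 0.25 * t), fs = 2)
  suppressMessages(f <- bandpass(s))
  expect_length(f$samples, 600)
  # passband amplitude within 5% and zero phase: cross-correlation peaks at lag 0
  expect_lt(abs(max(abs(f$samples)) - 1), 0.05)
  cc <- ccf(f$samples, s$samples, lag.max = 4, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  dc <- uniform_signal(rep(5, 600), fs = 2)
  suppressMessages(fdc <- bandpass(dc))
  expect_lt(max(abs(fdc$samples)), 5 * 1e-3)

  # 0.01 Hz lies deep in the stop band: analytic 4th-order Butterworth
  # high-pass response at 0.01/0.03 Hz, applied twice, is ~2e-8 in power
  slow <- uniform_signal(sin(2 * pi * 0.01 * (0:2399) / 2), fs = 2)
  suppressMessages(fs_ <- bandpass(slow))
  rms_ratio <- sqrt(mean(fs_$samples^2) / mean(slow$samples^2))
  expect_lt(rms_ratio, 0.25)

  # mean magnitude far below the sd after band-passing
  set.seed(4)
  noisy <- uniform_signal(rnorm(1200) + 3, fs = 2)
  suppressMessages(fn <- bandpass(noisy))
  expect_lt(abs(mean(fn$samples)), 0.01 * sd(fn$samples))
})

test_that("band-pass keeps both edges when Nyquist allows it", {
  t <- (0:2399) / 10
  inband <- uniform_signal(sin(2 * pi * 0.5 * t), fs = 10)
  outband <- uniform_signal(sin(2 * pi * 3 * t), fs = 10)
  expect_message(bandpass(inband, fs = NULL), NA)
  fi <- bandpass(inband)
  fo <- bandpass(outband)
  expect_gt(max(abs(fi$samples)), 0.9)
  expect_lt(sqrt(mean(fo$samples^2)), 0.05)
})

test_that("zero-phase filtering commutes with time reversal", {
  set.seed(11)
  x <- uniform_signal(rnorm(800), fs = 2)
  suppressMessages(a <- bandpass(x))
  suppressMessages(b <- bandpass(uniform_signal(rev(x$samples), fs = 2)))
  expect_lt(max(abs(a$samples - rev(b$samples))), 1e-8)
})

test_that("epoch segmentation drops the remainder and preserves the prefix", {
  n <- 1200 * 2  # 1200 s at 2 Hz
  resp <- uniform_signal(sin((1:n) / 50), fs = 2, label = "resp")
  hrv <- uniform_signal(cos((1:n) / 70), fs = 2, label = "hrv")
  eps <- segment_epochs(resp, hrv)
  expect_length(eps, 4L)
  expect_true(all(vapply(eps, function(e) length(e$resp$samples), numeric(1)) == 600))
  expect_equal(vapply(eps, function(e) e$start_time, numeric(1)), c(0, 300, 600, 900))
  recon <- unlist(lapply(eps, function(e) e$resp$samples))
  expect_identical(recon, resp$samples[seq_along(recon)])

  short <- uniform_signal(rnorm(598), fs = 2)  # 299 s record
  expect_length(segment_epochs(short, short), 0L)
  expect_error(segment_epochs(resp, uniform_signal(rnorm(10), fs = 2)), "equal length")
})

test_that("Welch PSD satisfies Parseval and localizes peaks", {
  set.seed(2)
  wn <- uniform_signal(rnorm(600), fs = 2)
  p <- welch_psd(wn)
  expect_lt(abs(p$total_power - var(wn$samples)) / var(wn$samples), 0.15)
  # stored total power is the trapezoidal integral of the density
  expect_equal(p$total_power,
               sum(diff(p$freqs) * (p$power[-1] + p$power[-length(p$power)])) / 2,
               tolerance = 1e-9)

  tone <- uniform_signal(sin(2 * pi * 0.3 * (0:599) / 2), fs = 2)
  pt <- welch_psd(tone)
  expect_lt(abs(pt$freqs[which.max(pt$power)] - 0.3), diff(pt$freqs)[1] + 1e-12)

  const <- uniform_signal(rep(2, 600), fs = 2)
  pc <- welch_psd(const)
  expect_equal(pc$freqs[which.max(pc$power)], 0)

  expect_error(welch_psd(uniform_signal(rnorm(30), fs = 2)), "shorter than one")
})

test_that("resampling preserves a slow tone and signal round-trips through CSV", {
  t <- (0:9999) / 100
  s <- uniform_signal(sin(2 * pi * 0.2 * t), fs = 100)
  r <- resample_signal(s, fs_out = 2)
  expect_equal(r$fs, 2)
  expect_lt(abs(max(abs(r$samples[50:150])) - 1), 0.05)

  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(r, path)
  back <- read_signal_csv(path)
  expect_equal(back$fs, r$fs, tolerance = 1e-9)
  expect_equal(back$samples, r$samples, tolerance = 1e-12)
})
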