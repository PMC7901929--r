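# Shared fixture builders: all fixtures are generated in code at test time.

# Narrow-band AR(2) "respiration-like" series (the same second-order
# oscillator shape the simulator uses), unit nominal innovation scale.
ar2_series <- function(n, seed, sd = 0.1) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = c(1.2, -0.7)), n, sd = sd))
}

# Linearly coupled pair: y(n) = gain * x(n-1) + noise_sd * white noise.
linear_pair <- function(n, seed, gain = 1, noise_sd = 0.1) {
  x <- ar2_series(n, seed)
  set.seed(seed + 1L)
  y <- gain * c(0, x[-n]) + noise_sd * stats::sd(x) * stats::rnorm(n)
  list(x = x, y = y)
}

# Quadratically coupled pair: y(n) = x(n-1)^2 (mean-removed) + noise.
quadratic_pair <- function(n, seed, noise_sd = 0.1) {
  x <- ar2_series(n, seed)
  q <- c(0, x[-n]^2)
  q <- q - mean(q)
  set.seed(seed + 1L)
  y <- q + noise_sd * stats::sd(q) * stats::rnorm(n)
  list(x = x, y = y)
}

# Hand-built PSD object for order-selection tests.
make_psd <- function(freqs, power) {
  structure(list(freqs = freqs, power = power,
                 total_power = sum(diff(freqs) * (power[-1] + power[-length(power)])) / 2),
            class = "rsa_psd")
}
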