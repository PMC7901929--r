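# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths (and libsvm): brute-force linear algebra and a
# generic projected-gradient solver for the constrained dual QP.

# Projection of v onto {z in [0, cap]^m : a'z = 0}, a in {+1,-1}^m. The map
# g(lambda) = a' clip(v - lambda*a, 0, cap) is continuous, non-increasing and
# piecewise linear with breakpoints a*v and a*(v - cap); the root is found
# exactly by linear interpolation between the bracketing breakpoints.
project_box_zerosum <- function(v, a, cap) {
  g <- function(lam) sum(a * pmin(pmax(v - lam * a, 0), cap))
  bp <- sort(c(a * v, a * (v - cap)))
  gv <- vapply(bp, g, numeric(1))
  i <- which(gv <= 0)[1L]
  lam <- if (is.na(i)) {
    bp[length(bp)]
  } else if (i == 1L || gv[i] == 0) {
    bp[i]
  } else {
    bp[i - 1L] + (bp[i] - bp[i - 1L]) * gv[i - 1L] / (gv[i - 1L] - gv[i])
  }
  pmin(pmax(v - lam * a, 0), cap)
}

# Generic accelerated projected-gradient (FISTA) solve of the eps-SVR dual:
#   min over (alpha, alpha*) in [0,c]^{2N}, sum(alpha - alpha*) = 0 of
#   0.5 (a-a*)' K (a-a*) + eps * sum(a+a*) - y'(a-a*)
# Returns the dual objective in the maximization form used by svr_fit().
oracle_svr_dual <- function(K, y, cost, epsilon, iters = 60000L) {
  N <- length(y)
  a <- c(rep(1, N), rep(-1, N))
  lip <- 2 * max(abs(eigen(K, symmetric = TRUE, only.values = TRUE)$values)) + 1e-12
  grad <- function(z) {
    beta <- z[1:N] - z[(N + 1):(2 * N)]
    kb <- as.numeric(K %*% beta)
    c(kb + epsilon - y, -kb + epsilon + y)
  }
  fobj <- function(z) {
    beta <- z[1:N] - z[(N + 1):(2 * N)]
    0.5 * sum(beta * (K %*% beta)) + epsilon * sum(z) - sum(y * beta)
  }
  z <- rep(0, 2 * N)
  w <- z
  t_acc <- 1
  f_prev <- Inf
  for (k in seq_len(iters)) {
    z_new <- project_box_zerosum(w - grad(w) / lip, a, cost)
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    w <- z_new + ((t_acc - 1) / t_new) * (z_new - z)
    if (k %% 250L == 0L) {
      f_now <- fobj(z_new)
      if (f_now > fobj(z) + 1e-14) {
        w <- z_new  # restart acceleration when the objective backslides
        t_new <- 1
      }
      if (abs(f_prev - f_now) < 1e-13 * max(1, abs(f_now))) {
        z <- z_new
        break
      }
      f_prev <- f_now
    }
    z <- z_new
    t_acc <- t_new
  }
  list(z = z, objective = -fobj(z),
       beta = z[1:N] - z[(N + 1):(2 * N)])
}

# Closed-form stationary variance of the AR(2) process
# x(n) = phi1 x(n-1) + phi2 x(n-2) + e(n), Var(e) = s2 (Yule-Walker).
ar2_stationary_var <- function(phi1, phi2, s2) {
  s2 * (1 - phi2) / ((1 + phi2) * ((1 - phi2)^2 - phi1^2))
}

# Raw periodogram total power over all positive-frequency bins.
periodogram_power <- function(v) {
  n <- length(v)
  sp <- Mod(stats::fft(v - mean(v)))^2 / n
  sum(sp[2:ceiling(n / 2)])
}
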