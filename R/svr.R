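#' Rule-of-thumb regularization and tube width for the HRV regression
#'
#' The regularization constant c is set to the normalized interquartile range
#' of the HRV, IQR(y)/1.349 -- a robust estimate of the response standard
#' deviation -- and the epsilon-insensitive tube width to c/10.
#'
#' @param y Numeric HRV vector (length >= 8, non-constant).
#' @return List with `c` and `epsilon`.
#' @export
#'
#' @examples
#' tune_c_epsilon(rnorm(100))
tune_c_epsilon <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 8L) stop("need at least 8 samples to estimate the IQR")
  iqr <- stats::IQR(y)
  if (iqr <= 0) stop("constant response: zero IQR, cannot tune c")
  c_val <- iqr / 1.349
  list(c = c_val, epsilon = c_val / 10)
}

#' RBF bandwidth by maximum kernel-matrix entropy
#'
#' Selects the Gaussian kernel bandwidth sigma^2 as the candidate maximizing
#' the Shannon entropy of the kernel-matrix entries. Candidates are 21
#' log-spaced values spanning `10^-2` to `10^2` times the median squared
#' pairwise distance between regressor rows; for each, the off-diagonal
#' entries `exp(-d2 / sigma2)` are binned into a 30-bin histogram on \[0, 1\]
#' and the entropy of the bin proportions is computed. Small bandwidths push
#' all entries to 0 and large ones to 1 (both low entropy); the maximizer
#' spreads the kernel values. Ties take the smallest candidate. Deterministic.
#'
#' @param X Regressor matrix (>= 10 rows).
#' @return Selected `sigma2` (positive scalar), with the candidate grid and
#'   entropies attached as attributes `"grid"` and `"entropy"`.
#' @export
tune_sigma2 <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 10L) stop("need at least 10 rows to tune sigma2")
  d2 <- as.numeric(stats::dist(X))^2  # off-diagonal squared distances (each pair once)
  dbar <- stats::median(d2)
  if (dbar <= 0) stop("degenerate design: all rows identical")
  grid <- dbar * 10^seq(-2, 2, length.out = 21L)
  ent <- vapply(grid, function(s2) {
    k <- exp(-d2 / s2)
    cnt <- tabulate(pmin(floor(k * 30) + 1L, 30L), nbins = 30L)
    pr <- cnt / length(k)
    pr <- pr[pr > 0]
    -sum(pr * log(pr))
  }, numeric(1L))
  s2 <- grid[which.max(ent)]  # which.max takes the first (smallest) on ties
  attr(s2, "grid") <- grid
  attr(s2, "entropy") <- ent
  s2
}

# Evaluate fn() while diverting both console streams (C-level solver
# chatter included) into a character log; sinks are restored on exit.
capture_console <- function(fn) {
  log_lines <- character()
  con <- textConnection("log_lines", open = "w", local = TRUE)
  sink(con, type = "output")
  sink(con, type = "message")
  restored <- FALSE
  restore <- function() {
    if (!restored) {
      sink(type = "message")
      sink(type = "output")
      close(con)
      restored <<- TRUE
    }
  }
  on.exit(restore(), add = TRUE)
  value <- tryCatch(fn(), error = function(e) {
    restore()
    stop(e)
  })
  restore()  # flush before reading the log
  list(value = value, log = log_lines)
}

# Kernel matrix between row sets A (m x L) and B (n x L).
kernel_matrix <- function(A, B, kernel) {
  if (kernel$kind == "linear") {
    A %*% t(B)
  } else {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    d2[d2 < 0] <- 0
    exp(-d2 / kernel$sigma2)
  }
}

#' Kernel specification
#' @param kind `"linear"` or `"rbf"`.
#' @param sigma2 RBF bandwidth (required iff `kind == "rbf"`).
#' @return List of class `rsa_kernel`.
#' @export
kernel_spec <- function(kind = c("linear", "rbf"), sigma2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "rbf") {
    if (is.null(sigma2) || !is.finite(sigma2) || sigma2 <= 0) {
      stop("RBF kernel requires positive 'sigma2'")
    }
  } else if (!is.null(sigma2)) {
    stop("'sigma2' only applies to the RBF kernel")
  }
  structure(list(kind = kind, sigma2 = sigma2), class = "rsa_kernel")
}

#' Fit an epsilon-SVR of present HRV on past respiration
#'
#' Solves the epsilon-insensitive support vector regression in its dual form
#' (box constraints \[0, c\] on each Lagrange multiplier pair, zero-sum
#' equality constraint) and returns the dual solution. Feasibility of the
#' returned multipliers is asserted, not assumed.
#'
#' @param X Regressor matrix (rows = training points, columns = lags).
#' @param y Response vector.
#' @param kernel An `rsa_kernel` from [kernel_spec()].
#' @param cost Regularization constant c (> 0).
#' @param epsilon Tube half-width (> 0).
#' @param tol Solver termination tolerance.
#' @return Object of class `rsa_svr`: `dual_coeffs` (alpha - alpha*, full
#'   length), `bias`, `kernel`, `X`, `y`, `cost`, `epsilon`, `objective`
#'   (dual objective, maximization form), `n_support`.
#' @export
svr_fit <- function(X, y, kernel, cost, epsilon, tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(inherits(kernel, "rsa_kernel"))
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (cost <= 0 || epsilon <= 0) stop("'cost' and 'epsilon' must be positive")
  # libsvm reports hitting its internal iteration cap by printing to the
  # console; capture that as a convergence flag (the returned dual iterate
  # is still feasible -- asserted below -- and is kept)
  fit_expr <- function() {
    if (kernel$kind == "linear") {
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = "linear",
                 cost = cost, epsilon = epsilon, scale = FALSE, tolerance = tol,
                 fitted = FALSE)
    } else {
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                 gamma = 1 / kernel$sigma2, cost = cost, epsilon = epsilon,
                 scale = FALSE, tolerance = tol, fitted = FALSE)
    }
  }
  captured <- capture_console(fit_expr)
  m <- captured$value
  converged <- !any(grepl("max number of iterations", captured$log))
  beta <- numeric(nrow(X))
  beta[m$index] <- as.numeric(m$coefs)
  # dual feasibility: alpha = max(beta, 0), alpha* = max(-beta, 0) in [0, c]
  slack <- 1e-6 * cost + 1e-12
  if (any(abs(beta) > cost + slack)) stop("solver returned infeasible multipliers")
  if (abs(sum(beta)) > 1e-4 * cost * sqrt(length(beta))) {
    stop("zero-sum dual constraint violated")
  }
  K <- kernel_matrix(X, X, kernel)
  obj <- -0.5 * drop(t(beta) %*% K %*% beta) - epsilon * sum(abs(beta)) +
    sum(y * beta)
  structure(list(dual_coeffs = beta, bias = -m$rho, kernel = kernel,
                 X = X, y = y, cost = cost, epsilon = epsilon,
                 objective = obj, converged = converged,
                 n_support = sum(abs(beta) > 1e-8 * cost)),
            class = "rsa_svr")
}

#' @export
print.rsa_svr <- function(x, ...) {
  cat(sprintf("<rsa_svr> %s kernel%s, N = %d, support vectors = %d, c = %.4g, eps = %.4g\n",
              x$kernel$kind,
              if (x$kernel$kind == "rbf") sprintf(" (sigma2 = %.4g)", x$kernel$sigma2) else "",
              length(x$y), x$n_support, x$cost, x$epsilon))
  invisible(x)
}

#' In-sample SVR prediction
#'
#' Evaluates the fitted expansion sum_n (alpha_n - alpha*_n) K(x, x_n) + b at
#' every training row (the in-sample prediction used for the
#' explained-variance indices).
#'
#' @param model An `rsa_svr`.
#' @param newX Optional matrix of evaluation rows; defaults to the training
#'   design.
#' @return Numeric vector of predictions.
#' @export
predict_in_sample <- function(model, newX = NULL) {
  stopifnot(inherits(model, "rsa_svr"))
  if (is.null(newX)) newX <- model$X
  K <- kernel_matrix(as.matrix(newX), model$X, model$kernel)
  drop(K %*% model$dual_coeffs) + model$bias
}

#' Linear and nonlinear RSA indices for one epoch
#'
#' The full per-epoch quantification: builds the lagged design with order L,
#' tunes (c, epsilon) from the HRV and sigma^2 from the design, fits the
#' epsilon-SVR once with a linear and once with an RBF kernel, and converts
#' the in-sample predictions y_l and y_k into explained-variance fractions
#'
#'   Pxl = (y_l' y_l) / (y' y),   Pxk = (y_k' y_k) / (y' y),
#'
#' with predictions and response centered by the training mean of y so both
#' are variance fractions. The lagged respiration matrix is standardized by
#' its common standard deviation before the fits (respiration amplitude is
#' sensor-gain dependent; one shared scale keeps both indices invariant to
#' it without distorting the lag structure). The reference linear index Px
#' from the orthogonal subspace projection is computed on the same design. Pxl/Pxk may exceed 1
#' for an overfitted in-sample RBF prediction; such epochs are flagged
#' `ratio_gt_one`, never clipped.
#'
#' @param resp,hrv `uniform_signal`s or numeric vectors of equal length.
#' @param order `"auto"` (spectral rule of [select_order()]) or a fixed
#'   positive integer L.
#' @param fs Sampling rate when the channels are bare vectors (default 2).
#' @param tol SVR solver tolerance.
#' @return Object of class `rsa_coupling`: list with `Px`, `Pxl`, `Pxk`, `L`,
#'   `tuning` (c, epsilon, sigma2), `flags`, and the two fitted models.
#' @export
#'
#' @examples
#' x <- sin(2 * pi * 0.25 * (0:599) / 2) + 0.1 * rnorm(600)
#' y <- c(0, x[-600]) + 0.2 * rnorm(600)
#' coupling_indices(x, y, order = 8)
coupling_indices <- function(resp, hrv, order = "auto", fs = 2, tol = 1e-6) {
  resp <- as_uniform_signal(resp, fs, "resp")
  hrv <- as_uniform_signal(hrv, resp$fs, "hrv")
  if (length(resp$samples) != length(hrv$samples)) {
    stop("respiration and HRV must have equal length")
  }
  L <- resolve_order(resp, order)
  sub <- build_embedding(resp, L)
  y <- align_response(hrv, L)
  if (nrow(sub$Q) < L + 5L) stop("epoch too short for the selected order")

  flags <- character()
  pr <- osp_project(sub, y)
  flags <- union(flags, pr$flags)

  # regressors are standardized: respiration amplitude is sensor-gain
  # dependent, and dividing by one common sd makes Pxl/Pxk invariant to it
  x_sd <- stats::sd(sub$Q)
  if (x_sd == 0) stop("constant respiration: cannot fit the regression")
  X <- sub$Q / x_sd
  tn <- tune_c_epsilon(y)
  s2 <- as.numeric(tune_sigma2(X))
  fit_l <- svr_fit(X, y, kernel_spec("linear"), tn$c, tn$epsilon, tol = tol)
  fit_k <- svr_fit(X, y, kernel_spec("rbf", sigma2 = s2), tn$c, tn$epsilon, tol = tol)

  mu <- mean(y)
  ssy <- sum((y - mu)^2)
  yl <- predict_in_sample(fit_l) - mu
  yk <- predict_in_sample(fit_k) - mu
  Pxl <- sum(yl^2) / ssy
  Pxk <- sum(yk^2) / ssy
  if (Pxl > 1 || Pxk > 1) flags <- union(flags, "ratio_gt_one")

  structure(list(Px = pr$Px, Pxl = Pxl, Pxk = Pxk, L = L,
                 tuning = list(c = tn$c, epsilon = tn$epsilon, sigma2 = s2),
                 flags = flags, fit_linear = fit_l, fit_rbf = fit_k),
            class = "rsa_coupling")
}

# RBF-only explained-variance fraction for one (resp, hrv) pair at fixed L:
# the reduced pipeline used when recomputing Pxk on surrogate pairs, where
# the linear fit and the projection reference are not needed. Identical
# tuning and centering to coupling_indices().
pxk_index <- function(resp, hrv, L, tol = 1e-6) {
  sub <- build_embedding(resp, L)
  y <- align_response(hrv, L)
  x_sd <- stats::sd(sub$Q)
  if (x_sd == 0) stop("constant respiration: cannot fit the regression")
  X <- sub$Q / x_sd
  tn <- tune_c_epsilon(y)
  s2 <- as.numeric(tune_sigma2(X))
  fit_k <- svr_fit(X, y, kernel_spec("rbf", sigma2 = s2), tn$c, tn$epsilon,
                   tol = tol)
  mu <- mean(y)
  sum((predict_in_sample(fit_k) - mu)^2) / sum((y - mu)^2)
}

#' @export
print.rsa_coupling <- function(x, ...) {
  cat(sprintf("<rsa_coupling> L = %d | Px = %.3f  Pxl = %.3f  Pxk = %.3f%s\n",
              x$L, x$Px, x$Pxl, x$Pxk,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}
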