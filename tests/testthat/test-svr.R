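test_that("the IQR tuning rule gives c = IQR/1.349 and epsilon = c/10", {
  y <- seq(0, 2.698, length.out = 9)  # IQR (type-7 quantiles) = 1.349
  expect_equal(IQR(y), 1.349)
  tn <- tune_c_epsilon(y)
  expect_equal(tn$c, 1.0)
  expect_equal(tn$epsilon, 0.1)

  set.seed(1)
  z <- rnorm(200)
  t1 <- tune_c_epsilon(z)
  t2 <- tune_c_epsilon(4.2 * z)
  expect_equal(t2$c, 4.2 * t1$c)
  expect_equal(t2$epsilon, 4.2 * t1$epsilon)

  expect_error(tune_c_epsilon(rep(1, 50)), "IQR")
  expect_error(tune_c_epsilon(1:5), "at least 8")
})

test_that("entropy-based bandwidth selection is deterministic and interior", {
  set.seed(12)
  X <- matrix(rnorm(100 * 4), 100, 4)
  s2a <- tune_sigma2(X)
  s2b <- tune_sigma2(X)
  expect_identical(as.numeric(s2a), as.numeric(s2b))

  grid <- attr(s2a, "grid")
  ent <- attr(s2a, "entropy")
  dbar <- median(as.numeric(dist(X))^2)
  # interior selection within a factor 10 of the median heuristic, and both
  # grid extremes (kernel ~ 0 resp. ~ 1 everywhere) have lower entropy
  expect_gt(as.numeric(s2a), grid[1])
  expect_lt(as.numeric(s2a), grid[21])
  expect_gte(as.numeric(s2a), dbar / 10)
  expect_lte(as.numeric(s2a), dbar * 10)
  expect_gt(max(ent), ent[1])
  expect_gt(max(ent), ent[21])

  # brute-force oracle: recompute the entropy curve directly
  d2 <- as.numeric(dist(X))^2
  ent_oracle <- sapply(grid, function(s2) {
    k <- exp(-d2 / s2)
    p <- tabulate(pmin(floor(k * 30) + 1L, 30L), nbins = 30L) / length(k)
    p <- p[p > 0]
    -sum(p * log(p))
  })
  expect_equal(ent, ent_oracle, tolerance = 1e-12)
  expect_equal(as.numeric(s2a), grid[which.max(ent_oracle)])

  expect_error(tune_sigma2(matrix(1, 20, 3)), "identical")
  expect_error(tune_sigma2(X[1:5, ]), "at least 10")
})

test_that("a realizable linear target is fit inside the tube", {
  set.seed(3)
  x <- rnorm(120)
  sub <- build_embedding(x, L = 2)
  y <- 0.8 * sub$Q[, 1]
  fit <- svr_fit(sub$Q, y, kernel_spec("linear"), cost = 100, epsilon = 1e-6)
  expect_lt(max(abs(predict_in_sample(fit) - y)), 10 * 1e-6)
})

test_that("responses inside the epsilon-tube give the all-zero dual solution", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  y <- 0.001 * runif(30)  # |y| < epsilon = 0.05 everywhere
  fit <- svr_fit(X, y, kernel_spec("linear"), cost = 1, epsilon = 0.05)
  expect_true(all(fit$dual_coeffs == 0))
  expect_equal(fit$n_support, 0L)
  pred <- predict_in_sample(fit)
  expect_true(all(abs(pred - fit$bias) < 1e-12))
})

test_that("dual solutions are feasible and match the generic QP oracle", {
  set.seed(77)
  for (i in 1:6) {
    N <- sample(10:15, 1)
    X <- matrix(rnorm(N * 2), N, 2)
    y <- 0.8 * X[, 1] + 0.3 * rnorm(N)
    tn <- tune_c_epsilon(y)
    kern <- if (i %% 2) kernel_spec("linear") else kernel_spec("rbf", sigma2 = 2)
    fit <- svr_fit(X, y, kern, tn$c, tn$epsilon, tol = 1e-10)
    # box and zero-sum constraints
    expect_true(all(abs(fit$dual_coeffs) <= tn$c + 1e-10))
    expect_lt(abs(sum(fit$dual_coeffs)), 1e-6 * tn$c)
    K <- if (kern$kind == "linear") X %*% t(X) else exp(-as.matrix(dist(X))^2 / 2)
    oracle <- oracle_svr_dual(K, y, tn$c, tn$epsilon)
    expect_lt(abs(fit$objective - oracle$objective), 1e-6)
  }
})

test_that("predictions obey the kernel expansion identities", {
  set.seed(21)
  X <- matrix(rnorm(80), 40, 2)
  y <- X[, 1] - 0.5 * X[, 2] + 0.1 * rnorm(40)
  tn <- tune_c_epsilon(y)
  fit_l <- svr_fit(X, y, kernel_spec("linear"), tn$c, tn$epsilon)
  w <- colSums(fit_l$dual_coeffs * X)
  expect_lt(max(abs(predict_in_sample(fit_l) - (X %*% w + fit_l$bias))), 1e-10)

  fit_k <- svr_fit(X, y, kernel_spec("rbf", sigma2 = 1.5), tn$c, tn$epsilon)
  # recomputation oracle: evaluate the expansion by hand at the training rows
  K <- exp(-as.matrix(dist(X))^2 / 1.5)
  expect_lt(max(abs(predict_in_sample(fit_k) -
                      (K %*% fit_k$dual_coeffs + fit_k$bias))), 1e-10)
})

test_that("uncoupled noise yields small indices; quadratic coupling opens a Pxk gap", {
  for (s in 1:10) {
    set.seed(400 + s)
    x <- ar2_series(600, seed = 500 + s)
    y <- rnorm(600)
    cpl <- coupling_indices(x, y, order = 8)
    expect_lt(cpl$Px, 0.15)
    expect_lt(cpl$Pxl, 0.25)
  }

  pq <- quadratic_pair(600, seed = 600)
  cq <- coupling_indices(pq$x, pq$y, order = 8)
  expect_gt(cq$Pxk - cq$Pxl, 0.2)
})

test_that("strong linear coupling agrees with the projection reference", {
  pl <- linear_pair(600, seed = 700, gain = 1, noise_sd = 0.05)
  cl <- coupling_indices(pl$x, pl$y, order = 8)
  expect_lt(abs(cl$Pxl - cl$Px), 0.1)

  # epsilon -> 0, c -> large: the linear SVR converges to the projection
  sub <- build_embedding(pl$x, 8L)
  y <- align_response(pl$y, 8L)
  fit <- svr_fit(sub$Q, y, kernel_spec("linear"), cost = 1e3, epsilon = 1e-6)
  mu <- mean(y)
  pxl_limit <- sum((predict_in_sample(fit) - mu)^2) / sum((y - mu)^2)
  expect_lt(abs(pxl_limit - osp_project(sub, y)$Px), 0.02)
})

test_that("the index triple is deterministic and Pxk is respiration-scale invariant", {
  pl <- linear_pair(400, seed = 800, gain = 0.8, noise_sd = 0.3)
  a <- coupling_indices(pl$x, pl$y, order = 8)
  b <- coupling_indices(pl$x, pl$y, order = 8)
  expect_identical(a$Px, b$Px)
  expect_identical(a$Pxl, b$Pxl)
  expect_identical(a$Pxk, b$Pxk)
  # the reduced RBF-only path (used for surrogate recomputation) agrees
  expect_equal(rsacoupling:::pxk_index(pl$x, pl$y, L = 8L), a$Pxk,
               tolerance = 1e-12)

  sc <- coupling_indices(3.7 * pl$x, pl$y, order = 8)
  expect_equal(sc$Px, a$Px, tolerance = 1e-10)
  expect_equal(sc$Pxk, a$Pxk, tolerance = 1e-8)
  expect_equal(sc$Pxl, a$Pxl, tolerance = 1e-8)
})

test_that("kernel specifications are validated", {
  expect_error(kernel_spec("rbf"), "sigma2")
  expect_error(kernel_spec("linear", sigma2 = 1), "only applies")
  expect_error(svr_fit(matrix(1:10, 5), rnorm(5), kernel_spec("linear"),
                       cost = -1, epsilon = 0.1), "positive")
})
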