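test_that("uncoupled series are uncorrelated and runs are seed-deterministic", {
  a <- simulate_pair(0, 0, n_samples = 2000, burn_in = 500, seed = 101)
  expect_lt(abs(cor(a$x1$samples, a$x2$samples)), 0.15)
  b <- simulate_pair(0, 0, n_samples = 2000, burn_in = 500, seed = 101)
  expect_identical(a$x1$samples, b$x1$samples)
  expect_identical(a$x2$samples, b$x2$samples)
  d <- simulate_pair(0, 0, n_samples = 2000, burn_in = 500, seed = 102)
  expect_false(identical(a$x1$samples, d$x1$samples))
})

test_that("x1 matches the closed-form AR(2) stationary variance", {
  sim <- simulate_pair(0, 0, n_samples = 20000, burn_in = 500,
                       noise_scale = 0.1, seed = 7)
  v_true <- ar2_stationary_var(1.2, -0.7, 0.01)
  expect_lt(abs(var(sim$x1$samples) - v_true) / v_true, 0.10)
})

test_that("simulation rejects degenerate configurations", {
  expect_error(simulate_pair(0, 0, n_samples = 2), ">= 3")
  expect_error(simulate_pair(-0.1, 0), "non-negative")
  expect_error(simulate_pair(0, 0, noise_scale = 0), "positive")
  expect_error(simulate_pair(0, 0, burn_in = -1), ">= 0")
})

test_that("the default oscillator coefficients never produce non-finite samples", {
  for (s in 1:10) {
    sim <- simulate_pair(1.8, 0.2, n_samples = 5000, burn_in = 0, seed = s)
    expect_true(all(is.finite(sim$x1$samples)))
    expect_true(all(is.finite(sim$x2$samples)))
  }
})

test_that("with zero coupling the projected variance fraction stays small", {
  for (s in 1:10) {
    sim <- simulate_pair(0, 0, n_samples = 1000, burn_in = 200, seed = 300 + s)
    for (L in c(2L, 10L)) {
      sub <- build_embedding(sim$x1, L)
      px <- osp_project(sub, align_response(sim$x2, L))$Px
      expect_lt(px, 0.15)
    }
  }
})

test_that("scenario grids enforce the c2 = 2 - c1 constraint and reject bad input", {
  g <- scenario_grid("linear_plus_nonlinear")
  expect_equal(g$c2_values, 2 - g$c1_values)
  expect_equal(g$c1_values, seq(0, 1.8, by = 0.2))
  expect_equal(g$n_realizations, 20L)
  g0 <- scenario_grid("linear_only")
  expect_true(all(g0$c2_values == 0))
  expect_error(scenario_grid(c1_values = numeric(0)), "non-empty")
  expect_error(scenario_grid(c1_values = c(0.4, 0.2)), "increasing")
  expect_error(scenario_grid("linear_plus_nonlinear", c1_values = c(0, 2.2)),
               "c1 <= 2")
})

test_that("grid rows carry the scenario metadata and are reproducible", {
  g <- scenario_grid("linear_plus_nonlinear", c1_values = c(0.2, 1.6),
                     n_realizations = 2L, base_seed = 5L)
  df1 <- run_grid(g, n_samples = 400L, burn_in = 100L, order = 6L)
  df2 <- run_grid(g, n_samples = 400L, burn_in = 100L, order = 6L)
  expect_identical(df1, df2)
  expect_equal(nrow(df1), 4L)
  expect_equal(unique(df1$c2), 2 - unique(df1$c1))
  expect_true(all(c("scenario", "c1", "c2", "realization", "L", "sigma2",
                    "c", "epsilon", "Px", "Pxl", "Pxk",
                    "surrogate_significant", "error") %in% names(df1)))
  expect_true(all(df1$error == ""))
})

test_that("stronger linear coupling raises Pxl; pure quadratic coupling favors Pxk", {
  g_lin <- scenario_grid("linear_only", c1_values = c(0.2, 1.8),
                         n_realizations = 5L, base_seed = 21L)
  df <- run_grid(g_lin, n_samples = 600L, burn_in = 200L)
  med <- tapply(df$Pxl, df$c1, median)
  expect_gt(med[["1.8"]], med[["0.2"]])

  g_quad <- scenario_grid("linear_plus_nonlinear", c1_values = 0,
                          n_realizations = 5L, base_seed = 22L)
  dq <- run_grid(g_quad, n_samples = 600L, burn_in = 200L)
  expect_gt(median(dq$Pxk), median(dq$Pxl))
})
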