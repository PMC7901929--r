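#' Coupled autoregressive simulation of cardiorespiratory interaction
#'
#' Generates one realization of the two-series benchmark model
#'
#'   x1(n) = 1.2 x1(n-1) - 0.7 x1(n-2) + 0.1 e1(n)
#'   x2(n) = 0.5 x2(n-1) - C1 x1(n-1) - C2 x1(n-1)^2 + 0.1 e2(n)
#'
#' with e1, e2 independent standard normal streams. x1 plays the role of the
#' respiration (a stochastic narrow-band AR(2) oscillator), x2 that of the
#' HRV, driven linearly with strength C1 and quadratically with strength C2.
#' Initial conditions are zero and `burn_in` leading samples are discarded
#' from both series so transients never reach the analysis.
#'
#' @param c1 Linear coupling strength C1 (>= 0).
#' @param c2 Nonlinear (quadratic) coupling strength C2 (>= 0).
#' @param n_samples Retained length (>= 3).
#' @param burn_in Discarded initial samples (>= 0).
#' @param noise_scale Innovation standard deviation multiplier (default 0.1).
#' @param seed Integer seed; realizations are deterministic given the seed.
#' @return List with `x1` and `x2`, both `uniform_signal`s at a nominal 2 Hz
#'   (the analysis rate used for order selection).
#' @export
#'
#' @examples
#' sim <- simulate_pair(c1 = 1, c2 = 1, n_samples = 1000, seed = 7)
#' sim$x1
simulate_pair <- function(c1, c2, n_samples = 1000L, burn_in = 500L,
                          noise_scale = 0.1, seed = NULL) {
  if (c1 < 0 || c2 < 0) stop("coupling strengths must be non-negative")
  n_samples <- as.integer(n_samples)
  burn_in <- as.integer(burn_in)
  if (is.na(n_samples) || n_samples < 3L) stop("'n_samples' must be >= 3")
  if (is.na(burn_in) || burn_in < 0L) stop("'burn_in' must be >= 0")
  if (noise_scale <= 0) stop("'noise_scale' must be positive")
  total <- n_samples + burn_in
  noise <- with_seed(seed, list(e1 = stats::rnorm(total), e2 = stats::rnorm(total)))
  x1 <- numeric(total)
  x2 <- numeric(total)
  x1m1 <- 0; x1m2 <- 0; x2m1 <- 0
  for (n in seq_len(total)) {
    v1 <- 1.2 * x1m1 - 0.7 * x1m2 + noise_scale * noise$e1[n]
    v2 <- 0.5 * x2m1 - c1 * x1m1 - c2 * x1m1^2 + noise_scale * noise$e2[n]
    x1[n] <- v1
    x2[n] <- v2
    x1m2 <- x1m1; x1m1 <- v1; x2m1 <- v2
  }
  if (!all(is.finite(x1)) || !all(is.finite(x2))) {
    stop("simulation diverged (non-finite samples); check the coefficients")
  }
  keep <- (burn_in + 1L):total
  list(x1 = uniform_signal(x1[keep], fs = 2, label = "x1 (respiration)"),
       x2 = uniform_signal(x2[keep], fs = 2, label = "x2 (HRV)"))
}

#' Scenario grid for the simulation bench
#'
#' Defines the coupling sweep: C1 runs over `c1_values` (default 0 to 1.8 in
#' steps of 0.2) and C2 is 0 in the `linear_only` scenario or `2 - C1` in the
#' `linear_plus_nonlinear` scenario, so the joint interaction strength stays
#' fixed while its composition shifts.
#'
#' @param scenario `"linear_only"` or `"linear_plus_nonlinear"`.
#' @param c1_values Strictly increasing C1 values.
#' @param n_realizations Realizations per grid cell (default 20).
#' @param base_seed Integer seed from which per-cell seeds are derived.
#' @return List of class `rsa_scenario_grid`.
#' @export
scenario_grid <- function(scenario = c("linear_only", "linear_plus_nonlinear"),
                          c1_values = seq(0, 1.8, by = 0.2),
                          n_realizations = 20L, base_seed = 1L) {
  scenario <- match.arg(scenario)
  c1_values <- as.numeric(c1_values)
  if (length(c1_values) == 0L) stop("'c1_values' must be non-empty")
  if (any(diff(c1_values) <= 0)) stop("'c1_values' must be strictly increasing")
  if (any(c1_values < 0)) stop("'c1_values' must be non-negative")
  n_realizations <- as.integer(n_realizations)
  if (is.na(n_realizations) || n_realizations < 1L) {
    stop("'n_realizations' must be a positive integer")
  }
  c2_values <- if (scenario == "linear_only") rep(0, length(c1_values)) else 2 - c1_values
  if (any(c2_values < 0)) stop("scenario requires c1 <= 2 so that c2 = 2 - c1 >= 0")
  structure(list(scenario = scenario, c1_values = c1_values,
                 c2_values = c2_values, n_realizations = n_realizations,
                 base_seed = as.integer(base_seed)),
            class = "rsa_scenario_grid")
}

#' Run the simulation bench over a scenario grid
#'
#' For every (C1, realization) cell: simulate the pair, select the order
#' (spectral rule on x1 by default), compute the coupling triple
#' (Px, Pxl, Pxk), and optionally the surrogate nonlinearity verdict. Fit
#' failures are returned as flagged rows; the grid never aborts.
#'
#' @param grid An `rsa_scenario_grid`.
#' @param n_samples,burn_in,noise_scale Passed to [simulate_pair()].
#' @param order Order policy: `"auto"` or a fixed integer.
#' @param n_surrogates Surrogates per cell for the nonlinearity test;
#'   `0` skips the test (column filled with `NA`).
#' @param progress Print a line per grid cell.
#' @return A `data.frame` with one row per (c1, realization):
#'   `scenario, c1, c2, realization, L, sigma2, c, epsilon, Px, Pxl, Pxk,
#'   surrogate_significant, error`.
#' @export
run_grid <- function(grid, n_samples = 1000L, burn_in = 500L,
                     noise_scale = 0.1, order = "auto", n_surrogates = 0L,
                     progress = FALSE) {
  stopifnot(inherits(grid, "rsa_scenario_grid"))
  cells <- expand.grid(realization = seq_len(grid$n_realizations),
                       cell = seq_along(grid$c1_values))
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    ci <- cells$cell[k]
    r <- cells$realization[k]
    c1 <- grid$c1_values[ci]
    c2 <- grid$c2_values[ci]
    seed <- cell_seed(grid$base_seed, ci, r)
    row <- data.frame(scenario = grid$scenario, c1 = c1, c2 = c2,
                      realization = r, L = NA_integer_, sigma2 = NA_real_,
                      c = NA_real_, epsilon = NA_real_, Px = NA_real_,
                      Pxl = NA_real_, Pxk = NA_real_,
                      surrogate_significant = NA, error = "")
    res <- tryCatch({
      sim <- simulate_pair(c1, c2, n_samples, burn_in, noise_scale, seed)
      cpl <- coupling_indices(sim$x1, sim$x2, order = order)
      row$L <- cpl$L
      row$sigma2 <- cpl$tuning$sigma2
      row$c <- cpl$tuning$c
      row$epsilon <- cpl$tuning$epsilon
      row$Px <- cpl$Px
      row$Pxl <- cpl$Pxl
      row$Pxk <- cpl$Pxk
      if (n_surrogates > 0L) {
        v <- nonlinearity_test(sim$x1, sim$x2, order = cpl$L,
                               n_surrogates = n_surrogates,
                               seed = seed + 1L, coupling = cpl)
        row$surrogate_significant <- v$significant
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[k]] <- res
    if (progress) {
      cat(sprintf("c1 = %.1f r = %2d : Px = %.3f Pxl = %.3f Pxk = %.3f%s\n",
                  c1, r, res$Px, res$Pxl, res$Pxk,
                  if (nzchar(res$error)) paste0(" ERROR ", res$error) else ""))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$c1, out$realization), , drop = FALSE]
}

# Deterministic per-cell seed below 2^31.
cell_seed <- function(base_seed, cell_index, realization) {
  (as.integer(base_seed) + 7919L * as.integer(cell_index) +
     104729L * as.integer(realization)) %% 2147483629L
}

#' Largest C1 at which the RBF index beats the linear index
#'
#' Summarizes a scenario-grid result: per C1 cell a two-sided paired Wilcoxon
#' signed-rank test compares Pxk and Pxl over realizations; a cell "favors
#' Pxk" when p < alpha and the median paired difference is positive. Returns
#' the largest such C1 (NA when no cell qualifies).
#'
#' @param grid_df Output of [run_grid()].
#' @param alpha Significance level (default 0.05).
#' @return List with `c1_max` and the per-cell table `cells`
#'   (`c1, p_value, median_diff, favors_pxk`).
#' @export
crossover_c1 <- function(grid_df, alpha = 0.05) {
  ok <- grid_df[!is.na(grid_df$Pxk) & !is.na(grid_df$Pxl), , drop = FALSE]
  cells <- do.call(rbind, lapply(split(ok, ok$c1), function(d) {
    dif <- d$Pxk - d$Pxl
    p <- tryCatch(
      stats::wilcox.test(d$Pxk, d$Pxl, paired = TRUE, exact = FALSE)$p.value,
      error = function(e) NA_real_)
    data.frame(c1 = d$c1[1L], p_value = p, median_diff = stats::median(dif),
               favors_pxk = is.finite(p) && p < alpha && stats::median(dif) > 0)
  }))
  rownames(cells) <- NULL
  fav <- cells$c1[cells$favors_pxk]
  list(c1_max = if (length(fav)) max(fav) else NA_real_, cells = cells)
}
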