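#' Time-delay embedding of a respiration signal
#'
#' Builds the lagged-regressor matrix shared by the orthogonal-subspace
#' projection and the support-vector regressions: row n holds the L strictly
#' past respiration samples \[x(n-1), ..., x(n-L)\], aligned with the present
#' HRV sample y(n). The first usable index is n = L + 1 (1-based), so the
#' matrix has `length(resp) - L` rows.
#'
#' @param resp A `uniform_signal` or numeric vector (respiration).
#' @param L Embedding order (number of past samples), `1 <= L < n - 1`.
#' @return An object of class `rsa_subspace`: list with `Q` (matrix,
#'   (n-L) x L), `L`, `lag_set` (1:L) and `fs` (NA for bare vectors).
#' @export
#'
#' @examples
#' build_embedding(c(1, 2, 3, 4, 5), L = 2)$Q
build_embedding <- function(resp, L) {
  fs <- NA_real_
  if (inherits(resp, "uniform_signal")) {
    fs <- resp$fs
    resp <- resp$samples
  }
  resp <- as.numeric(resp)
  n <- length(resp)
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("'L' must be a positive integer")
  if (L >= n - 1L) {
    if (L == n - 1L) {
      # boundary: single usable row
    } else {
      stop("'L' too large for the signal length")
    }
  }
  rows <- n - L
  Q <- matrix(0, nrow = rows, ncol = L)
  for (j in seq_len(L)) {
    Q[, j] <- resp[(L + 1L - j):(n - j)]
  }
  structure(list(Q = Q, L = L, lag_set = seq_len(L), fs = fs),
            class = "rsa_subspace")
}

#' Align an HRV vector with an embedding
#'
#' Drops the first L samples of y so it pairs with the rows of
#' [build_embedding()].
#' @param y Numeric vector or `uniform_signal` (HRV), full epoch length.
#' @param L Embedding order used for the respiration.
#' @return Numeric vector of length `length(y) - L`.
#' @export
align_response <- function(y, L) {
  if (inherits(y, "uniform_signal")) y <- y$samples
  y <- as.numeric(y)
  if (L >= length(y)) stop("'L' too large for the response length")
  y[(L + 1L):length(y)]
}

#' Orthogonal subspace projection of HRV onto lagged respiration
#'
#' The reference linear RSA estimate: y is projected onto the column space of
#' the lagged-respiration matrix Q, i.e. yr = Q (Q'Q)^-1 Q' y, computed via a
#' rank-revealing QR factorization rather than the explicit inverse. Both y
#' and the columns of Q are mean-centered first, so
#' Px = (yr' yr) / (y' y) is the fraction of HRV *variance* linearly
#' explained by past respiration.
#'
#' @param sub An `rsa_subspace` from [build_embedding()].
#' @param y Numeric response vector, `length(y) == nrow(sub$Q)`.
#' @return List with `yr` (projection, centered scale), `residual`
#'   (y - yr), `Px` in \[0, 1\], `rank`, and `flags` (character; contains
#'   `"rank_deficient"` when Q has deficient column rank).
#' @export
osp_project <- function(sub, y) {
  stopifnot(inherits(sub, "rsa_subspace"))
  y <- as.numeric(y)
  Q <- sub$Q
  if (length(y) != nrow(Q)) stop("'y' must match the embedding rows")
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  if (ssy == 0) stop("'y' is constant; Px undefined")
  Qc <- sweep(Q, 2L, colMeans(Q))
  qrd <- qr(Qc)
  flags <- character()
  if (qrd$rank < ncol(Qc)) flags <- "rank_deficient"
  yr <- qr.fitted(qrd, yc)
  Px <- sum(yr^2) / ssy
  Px <- min(max(Px, 0), 1)  # guard rounding at the boundary
  list(yr = yr, residual = yc - yr, Px = Px, rank = qrd$rank, flags = flags)
}
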