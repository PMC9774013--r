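#' Embed a series into its trajectory (Hankel) matrix
#'
#' Stacks the `K = N - L + 1` consecutive length-`L` windows of a series as
#' the columns of an `L x K` matrix, the first stage of singular spectrum
#' analysis. The result has identical entries along every anti-diagonal:
#' `X[i, j] = x[i + j - 1]`.
#'
#' @param x Numeric vector, the series (finite values, length at least 3).
#' @param L Window length. Must satisfy `2 <= L <= (N + 1) / 2`, i.e.
#'   `L <= K`, so the matrix is not wider than it is tall.
#' @return An `L x K` numeric matrix.
#' @seealso [diag_average()] for the inverse (Hankelisation) operation.
#' @export
#' @examples
#' ssa_embed(1:5, 3)
ssa_embed <- function(x, L) {
  x <- as.numeric(x)
  if (length(x) < 3L || !all(is.finite(x)))
    stop("`x` must be a finite numeric series of length >= 3")
  N <- length(x)
  L <- as.integer(L)
  K <- N - L + 1L
  if (length(L) != 1L || is.na(L) || L < 2L || L > K)
    stop(sprintf("`L` must lie in [2, %d] (so that L <= K = N - L + 1) for N = %d",
                 (N + 1L) %/% 2L, N))
  matrix(x[outer(seq_len(L), 0:(K - 1L), "+")], nrow = L, ncol = K)
}

#' Singular value decomposition of a trajectory matrix
#'
#' Decomposes `X` into its singular triples \eqn{(\sqrt{\lambda_i}, U_i,
#' V_i)} so that \eqn{X = \sum_i \sqrt{\lambda_i} U_i V_i^T}. Singular
#' values below `tol` times the largest are treated as numerically zero
#' when determining the rank `d`.
#'
#' @param X Numeric matrix with finite entries (typically from
#'   [ssa_embed()]).
#' @param tol Relative cutoff deciding which singular values count towards
#'   the rank.
#' @return An object of class `"ssa_decomp"`: a list with elements
#'   `values` (the `d` retained singular values, non-increasing), `u`
#'   (`L x d` left vectors), `v` (`K x d` right vectors), `d` (numeric
#'   rank) and `X` (the input matrix).
#' @export
ssa_decompose <- function(X, tol = 1e-12) {
  if (!is.matrix(X) || length(X) == 0L)
    stop("`X` must be a non-empty numeric matrix")
  if (!all(is.finite(X)))
    stop("`X` contains non-finite entries")
  s <- svd(X)
  d <- sum(s$d > tol * s$d[1L])
  d <- max(d, 1L)
  structure(
    list(values = s$d[seq_len(d)],
         u = s$u[, seq_len(d), drop = FALSE],
         v = s$v[, seq_len(d), drop = FALSE],
         d = d,
         X = X),
    class = "ssa_decomp")
}

#' @export
print.ssa_decomp <- function(x, ...) {
  cat(sprintf("SSA decomposition: %d x %d trajectory matrix, numeric rank %d\n",
              nrow(x$X), ncol(x$X), x$d))
  cat("Leading singular values:",
      paste(signif(utils::head(x$values, 5L), 4L), collapse = ", "),
      if (x$d > 5L) "..." else "", "\n")
  invisible(x)
}

#' Split a decomposition into trend and residual matrices
#'
#' Sums the first `I` elementary matrices \eqn{X_i = \sqrt{\lambda_i} U_i
#' V_i^T} into a trend matrix and the remaining `d - I` into a residual
#' matrix; the two always add back to the original trajectory matrix.
#'
#' @param decomp An `"ssa_decomp"` object.
#' @param I Number of leading components assigned to the trend,
#'   `1 <= I <= d`.
#' @return List with matrices `trend` and `residual`.
#' @export
ssa_group <- function(decomp, I) {
  stopifnot(inherits(decomp, "ssa_decomp"))
  I <- as.integer(I)
  if (length(I) != 1L || is.na(I) || I < 1L || I > decomp$d)
    stop(sprintf("`I` must lie in [1, d = %d]", decomp$d))
  idx <- seq_len(I)
  trend <- decomp$u[, idx, drop = FALSE] %*%
    (decomp$values[idx] * t(decomp$v[, idx, drop = FALSE]))
  list(trend = trend, residual = decomp$X - trend)
}

#' Diagonal (anti-diagonal) averaging of a matrix into a series
#'
#' Hankelises an arbitrary `L x K` matrix: entry `g[i]` of the output is
#' the mean of all matrix entries `M[m, j]` with `m + j - 1 = i`. Applied
#' to a matrix from [ssa_embed()] this recovers the original series
#' exactly; applied to a grouped trend matrix (which need not be Hankel)
#' it yields the reconstructed trend series.
#'
#' @param M Non-empty numeric matrix.
#' @return Numeric vector of length `nrow(M) + ncol(M) - 1`.
#' @export
diag_average <- function(M) {
  if (!is.matrix(M) || length(M) == 0L)
    stop("`M` must be a non-empty numeric matrix")
  N <- nrow(M) + ncol(M) - 1L
  idx <- as.vector(row(M) + col(M) - 1L)
  m <- as.vector(M)
  counts <- tabulate(idx, nbins = N)
  g <- as.vector(rowsum(m, idx, reorder = TRUE)) / counts
  # second compensation pass (as in mean()): makes the round-trip from a
  # true Hankel matrix bit-exact
  g + as.vector(rowsum(m - g[idx], idx, reorder = TRUE)) / counts
}

# Shared SSA training step: decomposition, I-component reconstruction and
# the recurrent forecasting coefficients derived from the leading left
# singular vectors. `basis` may supply frozen left vectors (columns) to
# reuse a previously estimated signal subspace on a new window.
.ssa_train <- function(x, L, I, basis = NULL) {
  X <- ssa_embed(x, L)
  if (is.null(basis)) {
    dec <- ssa_decompose(X)
    if (I > dec$d)
      stop(sprintf("`I` = %d exceeds the numeric rank d = %d", I, dec$d))
    U <- dec$u[, seq_len(I), drop = FALSE]
    g <- ssa_group(dec, I)
    trend_mat <- g$trend
  } else {
    U <- basis
    trend_mat <- U %*% crossprod(U, X)
    dec <- NULL
  }
  recon <- diag_average(trend_mat)
  pi_ <- U[L, ]
  nu2 <- sum(pi_^2)
  coef <- if (nu2 < 1 - 1e-8)
    drop(U[-L, , drop = FALSE] %*% pi_) / (1 - nu2)
  else
    NULL
  list(recon = recon, coef = coef, nu2 = nu2, U = U, L = L, I = I,
       decomp = dec)
}

# Continue a reconstructed series with the linear recurrence `coef`.
.lrr_continue <- function(recon, coef, steps) {
  L <- length(coef) + 1L
  buf <- recon[(length(recon) - L + 2L):length(recon)]
  out <- numeric(steps)
  for (h in seq_len(steps)) {
    out[h] <- sum(coef * buf)
    buf <- c(buf[-1L], out[h])
  }
  out
}

#' Reconstruct the trend of a series by truncated SSA
#'
#' Convenience composition of [ssa_embed()], [ssa_decompose()],
#' [ssa_group()] and [diag_average()]: the series is embedded with window
#' `L`, the first `I` singular triples are kept, and the grouped matrix is
#' averaged back into a series of the original length. With `I` equal to
#' the numeric rank the input is recovered to floating tolerance.
#'
#' @inheritParams ssa_embed
#' @param I Number of leading components kept as trend.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' t <- 1:200
#' x <- 10 + sin(2 * pi * t / 17)
#' trend <- ssa_reconstruct(x, L = 50, I = 3)
#' max(abs(trend - x))  # noiseless signal of rank 3 is recovered
ssa_reconstruct <- function(x, L, I) {
  .ssa_train(x, L, I)$recon
}

#' Forecast a series by the SSA recurrent linear formula
#'
#' Reconstructs the trend from the first `I` singular triples and
#' continues it `steps` values past the end of the series using the
#' linear recurrence of order `L - 1` derived from the leading left
#' singular vectors: writing \eqn{\pi_i} for the last coordinate of
#' \eqn{U_i} and \eqn{\nu^2 = \sum_i \pi_i^2}, the recurrence
#' coefficients are \eqn{R = (1-\nu^2)^{-1} \sum_i \pi_i U_i^{\nabla}}
#' (the vectors with their last coordinate dropped), and each new value is
#' the inner product of `R` with the preceding `L - 1` values. The
#' forecast is fully deterministic.
#'
#' @inheritParams ssa_reconstruct
#' @param steps Number of values to forecast (0 returns an empty vector).
#' @return Numeric vector of length `steps`.
#' @export
#' @examples
#' ssa_forecast(rep(72, 40), L = 10, I = 1, steps = 5)  # constant continues
ssa_forecast <- function(x, L, I, steps) {
  steps <- as.integer(steps)
  if (length(steps) != 1L || is.na(steps) || steps < 0L)
    stop("`steps` must be a non-negative integer")
  if (steps == 0L) return(numeric(0))
  fit <- .ssa_train(x, L, I)
  if (is.null(fit$coef))
    stop(sprintf(paste0("degenerate recurrence: verticality coefficient ",
                        "%.6f >= 1; the signal subspace contains the last ",
                        "coordinate vector, no linear recurrence exists"),
                 fit$nu2))
  .lrr_continue(fit$recon, fit$coef, steps)
}
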