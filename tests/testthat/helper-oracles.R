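# Brute-force oracles, deliberately independent of the implementation.

# Anti-diagonal averaging by explicit double loop.
brute_diag_average <- function(M) {
  L <- nrow(M); K <- ncol(M); N <- L + K - 1L
  g <- numeric(N)
  for (i in seq_len(N)) {
    vals <- c()
    for (m in seq_len(L)) {
      j <- i - m + 1L
      if (j >= 1L && j <= K) vals <- c(vals, M[m, j])
    }
    g[i] <- mean(vals)
  }
  g
}

# Empirical copula by explicit counting.
brute_empirical_copula <- function(u, v, a, b) {
  cnt <- 0L
  for (i in seq_along(u)) if (u[i] <= a && v[i] <= b) cnt <- cnt + 1L
  cnt / length(u)
}

# Analytic copula CDFs written out directly from the family formulas,
# kept separate from the package's vectorised implementation.
oracle_cdf <- function(family, theta, u, v) {
  if (family == "clayton")
    return(max(u^(-theta) + v^(-theta) - 1, 0)^(-1 / theta))
  if (family == "frank")
    return(-log(1 + (exp(-theta * u) - 1) * (exp(-theta * v) - 1) /
                  (exp(-theta) - 1)) / theta)
  exp(-(((-log(u))^theta + (-log(v))^theta))^(1 / theta))
}
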