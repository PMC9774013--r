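# Bivariate Archimedean copula toolkit: Clayton, Frank and Gumbel families
# plus the independence copula, empirical copula on rank space, canonical
# maximum-likelihood fitting, Cramer-von-Mises family selection and
# conditional (h-function) sampling.

ARCHM_FAMILIES <- c("clayton", "frank", "gumbel")

# |theta| below this is a removable singularity for Clayton/Frank and is
# evaluated as the independence copula.
.INDEP_EPS <- 1e-8

# ML search bounds per family; Frank is capped where exp(|theta|) is still
# comfortably representable in the density.
.THETA_BOUNDS <- list(clayton = c(-0.95, 28),
                      frank   = c(-35, 35),
                      gumbel  = c(1, 30))

.check_theta <- function(family, theta) {
  if (family == "independence") return(invisible(NULL))
  if (length(theta) != 1L || !is.finite(theta))
    stop("`theta` must be a single finite number")
  ok <- switch(family,
               clayton = theta >= -1,
               frank   = TRUE,
               gumbel  = theta >= 1)
  if (!ok)
    stop(sprintf("theta = %g outside the %s domain (%s)", theta, family,
                 switch(family, clayton = "theta >= -1",
                        gumbel = "theta >= 1", frank = "finite")))
  invisible(NULL)
}

#' Construct an Archimedean copula model
#'
#' @param family One of `"clayton"`, `"frank"`, `"gumbel"` or
#'   `"independence"`. Parameter domains: Clayton `theta >= -1`, Frank any
#'   finite `theta`, Gumbel `theta >= 1`. For Clayton and Frank,
#'   `|theta| < 1e-8` is evaluated as the independence copula (the
#'   singularity at 0 is removable); Gumbel with `theta = 1` is exactly
#'   independence.
#' @param theta Dependence parameter (ignored for `"independence"`).
#' @return Object of class `"copula_model"`.
#' @export
#' @examples
#' cop <- copula_model("clayton", 2)
#' copula_cdf(cop, 0.5, 0.5)
copula_model <- function(family = c("clayton", "frank", "gumbel", "independence"),
                         theta = NULL) {
  family <- match.arg(family)
  if (family == "independence") {
    theta <- NA_real_
  } else {
    if (is.null(theta)) stop("`theta` is required for family ", family)
    theta <- as.numeric(theta)
    .check_theta(family, theta)
  }
  structure(list(family = family, theta = theta), class = "copula_model")
}

#' @export
print.copula_model <- function(x, ...) {
  if (x$family == "independence")
    cat("Independence copula\n")
  else
    cat(sprintf("%s copula, theta = %.4g\n", x$family, x$theta))
  if (!is.null(x$loglik))
    cat(sprintf("  fitted by ML on n = %d pseudo-observations, loglik = %.3f\n",
                x$n, x$loglik))
  invisible(x)
}

# Does the model evaluate as independence?
.is_indep <- function(model) {
  model$family == "independence" ||
    (model$family %in% c("clayton", "frank") && abs(model$theta) < .INDEP_EPS) ||
    (model$family == "gumbel" && model$theta == 1)
}

#' Rank-transform a sample to pseudo-observations
#'
#' Maps a numeric sample to the open unit interval via
#' `rank(x) / (n + 1)`, with average ranks for ties. The result is
#' invariant under any strictly increasing transform of `x`, which is
#' what makes the copula of a pair identifiable from ranks alone.
#'
#' @param x Numeric vector of length at least 2, finite values.
#' @return Numeric vector in (0, 1) of the same length.
#' @export
#' @examples
#' rank_transform(c(10, 20, 30))  # 0.25 0.50 0.75
rank_transform <- function(x) {
  if (length(x) < 2L)
    stop("`x` must have length >= 2")
  if (!all(is.finite(x)))
    stop("`x` contains non-finite values")
  rank(x, ties.method = "average") / (length(x) + 1)
}

#' Empirical copula of a bivariate sample of pseudo-observations
#'
#' The rank-based estimator
#' \eqn{C_e(a, b) = n^{-1} \sum_i 1(u_i \le a, v_i \le b)}, evaluated at
#' one or more points of the unit square. `a` and `b` are recycled to a
#' common length.
#'
#' @param u,v Pseudo-observations in (0, 1), equal length `n >= 1`.
#' @param a,b Evaluation points in \[0, 1\].
#' @return Numeric vector of copula values in \[0, 1\].
#' @export
empirical_copula <- function(u, v, a, b) {
  stopifnot(length(u) == length(v), length(u) >= 1L)
  if (any(a < 0 | a > 1 | b < 0 | b > 1))
    stop("evaluation points must lie in [0, 1]")
  pts <- cbind(a, b)  # recycles
  vapply(seq_len(nrow(pts)),
         function(k) mean(u <= pts[k, 1L] & v <= pts[k, 2L]),
         numeric(1))
}

# Empirical copula evaluated at the sample points themselves (the CvM
# statistic needs this); O(n^2) but vectorised.
.emp_cop_at_sample <- function(u, v) {
  colMeans(outer(u, u, "<=") & outer(v, v, "<="))
}

#' Archimedean generator function
#'
#' Evaluates the generator \eqn{\varphi(t)} of the family:
#' Clayton \eqn{(t^{-\theta} - 1)/\theta}, Frank
#' \eqn{-\log\{(e^{-\theta t} - 1)/(e^{-\theta} - 1)\}}, Gumbel
#' \eqn{(-\log t)^\theta}; the independence generator is \eqn{-\log t}.
#' Every generator satisfies `phi(1) = 0` and is non-increasing on (0, 1].
#'
#' @inheritParams copula_model
#' @param t Evaluation points in (0, 1].
#' @return Numeric vector of non-negative generator values.
#' @export
copula_generator <- function(family, theta = NULL, t) {
  family <- match.arg(family, c(ARCHM_FAMILIES, "independence"))
  if (any(t <= 0 | t > 1)) stop("`t` must lie in (0, 1]")
  if (family == "independence") return(-log(t))
  .check_theta(family, theta)
  if (family != "gumbel" && abs(theta) < .INDEP_EPS) return(-log(t))
  switch(family,
         clayton = (t^(-theta) - 1) / theta,
         frank   = -log(expm1(-theta * t) / expm1(-theta)),
         gumbel  = (-log(t))^theta)
}

#' Copula cumulative distribution function
#'
#' Evaluates \eqn{C_\theta(u, v)} for the model's family:
#' Clayton \eqn{\max(u^{-\theta} + v^{-\theta} - 1, 0)^{-1/\theta}},
#' Frank \eqn{-\theta^{-1} \log\{1 + (e^{-\theta u} - 1)(e^{-\theta v} - 1)
#' / (e^{-\theta} - 1)\}}, Gumbel
#' \eqn{\exp[-((-\log u)^\theta + (-\log v)^\theta)^{1/\theta}]}.
#' All satisfy the grounded boundary `C(u,0) = C(0,v) = 0` and the margin
#' identities `C(u,1) = u`, `C(1,v) = v`.
#'
#' @param model A [copula_model()].
#' @param u,v Values in \[0, 1\] (recycled to a common length).
#' @return Numeric vector of copula values in \[0, 1\].
#' @export
copula_cdf <- function(model, u, v) {
  stopifnot(inherits(model, "copula_model"))
  if (any(u < 0 | u > 1 | v < 0 | v > 1))
    stop("`u` and `v` must lie in [0, 1]")
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  if (.is_indep(model)) return(u * v)
  th <- model$theta
  switch(model$family,
    clayton = {
      out <- numeric(n)
      pos <- u > 0 & v > 0
      s <- pmax(u[pos]^(-th) + v[pos]^(-th) - 1, 0)
      out[pos] <- ifelse(is.finite(s), pmax(s, 0)^(-1 / th), 0)
      if (th < 0) out[!pos] <- 0
      out
    },
    frank = {
      -log1p(expm1(-th * u) * expm1(-th * v) / expm1(-th)) / th
    },
    gumbel = {
      out <- numeric(n)
      pos <- u > 0 & v > 0
      out[pos] <- exp(-((-log(u[pos]))^th + (-log(v[pos]))^th)^(1 / th))
      out
    })
}

#' Conditional copula distribution (h-function)
#'
#' The conditional CDF of `V` given `U = given_u`, i.e. the partial
#' derivative \eqn{h(v \mid u) = \partial C(u, v) / \partial u}. It is
#' non-decreasing in `v` with limits 0 and 1, and is the basis of
#' conditional sampling by inverse transform.
#'
#' @param model A [copula_model()].
#' @param v Evaluation points in (0, 1).
#' @param given_u Conditioning value in (0, 1) (scalar or recycled).
#' @return Numeric vector of conditional probabilities in \[0, 1\].
#' @export
conditional_cdf <- function(model, v, given_u) {
  stopifnot(inherits(model, "copula_model"))
  if (any(v <= 0 | v >= 1) || any(given_u <= 0 | given_u >= 1))
    stop("`v` and `given_u` must lie strictly inside (0, 1)")
  n <- max(length(v), length(given_u))
  v <- rep_len(v, n); u <- rep_len(given_u, n)
  if (.is_indep(model)) return(v)
  th <- model$theta
  switch(model$family,
    clayton = {
      s <- u^(-th) + v^(-th) - 1
      ifelse(s > 0, u^(-th - 1) * s^(-1 / th - 1), 0)
    },
    frank = {
      exp(-th * u) * expm1(-th * v) /
        (expm1(-th) + expm1(-th * u) * expm1(-th * v))
    },
    gumbel = {
      x <- -log(u); y <- -log(v)
      s <- x^th + y^th
      copula_cdf(model, u, v) * s^(1 / th - 1) * x^(th - 1) / u
    })
}

# Inverse of the h-function in its `v` argument. Closed forms for Clayton
# (theta > 0) and Frank; monotone bisection elsewhere (tol 1e-10, <= 200
# iterations, vectorised).
.conditional_quantile <- function(model, p, given_u) {
  n <- max(length(p), length(given_u))
  p <- rep_len(p, n); u <- rep_len(given_u, n)
  if (.is_indep(model)) return(p)
  th <- model$theta
  if (model$family == "clayton" && th > 0) {
    v <- (1 + u^(-th) * (p^(-th / (th + 1)) - 1))^(-1 / th)
    return(pmin(pmax(v, 1e-12), 1 - 1e-12))
  }
  if (model$family == "frank") {
    a <- expm1(-th); cu <- expm1(-th * u)
    b <- p * a / (1 + cu * (1 - p))
    v <- -log1p(b) / th
    return(pmin(pmax(v, 1e-12), 1 - 1e-12))
  }
  lo <- rep(1e-12, n); hi <- rep(1 - 1e-12, n)
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    below <- conditional_cdf(model, mid, u) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-10) break
  }
  (lo + hi) / 2
}

#' Conditional quantile of a copula (inverse h-function)
#'
#' Solves \eqn{h(v \mid u) = p} for `v`. Clayton (positive dependence)
#' and Frank use their closed-form inverses; other cases use monotone
#' bisection to absolute tolerance 1e-10.
#'
#' @param model A [copula_model()].
#' @param p Probabilities in (0, 1).
#' @param given_u Conditioning value(s) in (0, 1).
#' @return Numeric vector of quantiles in (0, 1).
#' @export
conditional_quantile <- function(model, p, given_u) {
  stopifnot(inherits(model, "copula_model"))
  if (any(p <= 0 | p >= 1) || any(given_u <= 0 | given_u >= 1))
    stop("`p` and `given_u` must lie strictly inside (0, 1)")
  .conditional_quantile(model, p, given_u)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. A NULL seed uses (and
# advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample from the conditional copula distribution
#'
#' Draws `n` iid values of `V` given `U = given_u` by inverse-transform
#' sampling on the h-function: `v = h^{-1}(w | u)` with `w` uniform.
#' Reproducible under a fixed `seed`; the caller's RNG state is left
#' untouched when a seed is given.
#'
#' @param model A [copula_model()].
#' @param given_u Conditioning value in (0, 1).
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` in (0, 1).
#' @export
conditional_sample <- function(model, given_u, n, seed = NULL) {
  stopifnot(inherits(model, "copula_model"), n >= 1)
  if (length(given_u) != 1L || given_u <= 0 || given_u >= 1)
    stop("`given_u` must be a single value strictly inside (0, 1)")
  w <- with_seed(seed, stats::runif(n))
  .conditional_quantile(model, w, given_u)
}

#' Sample bivariate pairs from a copula
#'
#' Draws `n` pairs `(u, v)` with uniform margins and the model's
#' dependence structure: `u` uniform, then `v = h^{-1}(w | u)`.
#'
#' @inheritParams conditional_sample
#' @return An `n x 2` matrix with columns `u`, `v`.
#' @export
sample_copula <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "copula_model"), n >= 1)
  uw <- with_seed(seed, matrix(stats::runif(2 * n), ncol = 2L))
  u <- uw[, 1L]
  v <- .conditional_quantile(model, uw[, 2L], u)
  cbind(u = u, v = v)
}

# Copula log-density summed over a sample of pseudo-observations.
# Returns -Inf wherever the parameter puts zero density on a data point.
.copula_loglik <- function(family, theta, u, v) {
  if (family != "gumbel" && abs(theta) < .INDEP_EPS) return(0)
  if (family == "gumbel" && theta == 1) return(0)
  ll <- switch(family,
    clayton = {
      s <- u^(-theta) + v^(-theta) - 1
      if (any(s <= 0)) return(-Inf)
      length(u) * log1p(theta) -
        (1 + theta) * sum(log(u) + log(v)) -
        (2 + 1 / theta) * sum(log(s))
    },
    frank = {
      dnm <- -expm1(-theta) - expm1(-theta * u) * expm1(-theta * v)
      length(u) * log(theta * (-expm1(-theta))) -
        theta * sum(u + v) - 2 * sum(log(abs(dnm)))
    },
    gumbel = {
      x <- -log(u); y <- -log(v)
      s <- x^theta + y^theta
      a <- s^(1 / theta)
      sum(-a + (theta - 1) * (log(x) + log(y)) - log(u) - log(v) +
            (1 / theta - 2) * log(s) + log(a + theta - 1))
    })
  if (!is.finite(ll)) -Inf else ll
}

#' Fit an Archimedean copula by maximum likelihood
#'
#' Canonical ML: the copula log-density is maximised over the family's
#' parameter domain with the margins handled empirically, i.e. the inputs
#' are pseudo-observations (see [rank_transform()]). The 1-D likelihood
#' is maximised by golden-section search over a bounded domain
#' (Clayton \[-0.95, 28\], Frank \[-35, 35\], Gumbel \[1, 30\]) and the
#' result is cross-checked against the domain endpoints and the
#' independence value so boundary optima (e.g. Gumbel at
#' \eqn{\theta = 1} for independent data) are returned exactly.
#'
#' @param u,v Pseudo-observations in (0, 1), equal length `n >= 10`.
#' @param family `"clayton"`, `"frank"` or `"gumbel"`.
#' @return A [copula_model()] with extra fields `loglik` and `n`.
#' @export
#' @examples
#' set.seed(1)
#' uv <- sample_copula(copula_model("clayton", 2), 500)
#' fit_copula(rank_transform(uv[, 1]), rank_transform(uv[, 2]), "clayton")
fit_copula <- function(u, v, family = c("clayton", "frank", "gumbel")) {
  family <- match.arg(family)
  stopifnot(length(u) == length(v))
  if (length(u) < 10L)
    stop("ML fitting needs at least 10 observations")
  if (any(u <= 0 | u >= 1 | v <= 0 | v >= 1))
    stop("`u`, `v` must be pseudo-observations strictly inside (0, 1)")
  bounds <- .THETA_BOUNDS[[family]]
  nll <- function(th) {
    val <- .copula_loglik(family, th, u, v)
    if (is.finite(val)) -val else .Machine$double.xmax
  }
  opt <- stats::optimize(nll, interval = bounds, tol = 1e-6)
  # candidate set: interior optimum, endpoints, independence
  cand <- c(opt$minimum, bounds)
  cand <- c(cand, if (family == "gumbel") 1 else 0)
  cand <- unique(pmin(pmax(cand, bounds[1L]), bounds[2L]))
  ll <- vapply(cand, function(th) .copula_loglik(family, th, u, v), numeric(1))
  if (all(!is.finite(ll)))
    stop("ML fit failed to find a parameter with finite likelihood for ",
         family)
  theta <- cand[which.max(ll)]
  out <- copula_model(family, theta)
  out$loglik <- max(ll)
  out$n <- length(u)
  out
}

#' Select the best-fitting copula family by goodness of fit
#'
#' Fits the Clayton, Frank and Gumbel copulas to the pseudo-observations
#' by maximum likelihood and computes, for each, the Cramer-von-Mises
#' distance \eqn{\sum_i \{C_e(u_i, v_i) - C_\theta(u_i, v_i)\}^2} between
#' the fitted copula and the empirical copula evaluated at the sample.
#' The family attaining the minimum distance is selected. If every fit
#' fails the independence copula is returned (with a warning).
#'
#' @param u,v Pseudo-observations in (0, 1), equal length `n >= 30`.
#' @param families Candidate families (default all three).
#' @return Object of class `"copula_gof"`: list with `selected` (the
#'   winning [copula_model()]), `table` (data frame of family, theta,
#'   CvM distance, log-likelihood) and `n`.
#' @export
select_copula <- function(u, v, families = ARCHM_FAMILIES) {
  stopifnot(length(u) == length(v))
  if (length(u) < 30L)
    stop("family selection needs at least 30 observations")
  ce <- .emp_cop_at_sample(u, v)
  rows <- lapply(families, function(fam) {
    fit <- tryCatch(fit_copula(u, v, fam), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    dist <- sum((ce - copula_cdf(fit, u, v))^2)
    list(fit = fit,
         row = data.frame(family = fam, theta = fit$theta,
                          distance = dist, loglik = fit$loglik))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    warning("all copula fits failed; falling back to the independence copula")
    sel <- copula_model("independence")
    tab <- data.frame(family = "independence", theta = NA_real_,
                      distance = sum((ce - u * v)^2), loglik = 0)
  } else {
    tab <- do.call(rbind, lapply(rows, `[[`, "row"))
    best <- which.min(tab$distance)
    sel <- rows[[best]]$fit
  }
  structure(list(selected = sel, table = tab, n = length(u)),
            class = "copula_gof")
}

#' @export
print.copula_gof <- function(x, ...) {
  cat(sprintf("Copula family selection on n = %d pseudo-observations\n", x$n))
  print(x$table, row.names = FALSE)
  cat("selected:", x$selected$family, "\n")
  invisible(x)
}

#' Write / read a fitted copula model as a plain-text key-value file
#'
#' @param model A [copula_model()] (optionally carrying `loglik`, `n`).
#' @param path File path.
#' @return `read_copula_model()` returns a [copula_model()].
#' @export
write_copula_model <- function(model, path) {
  stopifnot(inherits(model, "copula_model"))
  lines <- c(paste0("family=", model$family),
             paste0("theta=", format(model$theta, digits = 17)),
             if (!is.null(model$n)) paste0("n=", model$n),
             if (!is.null(model$loglik))
               paste0("loglik=", format(model$loglik, digits = 17)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_copula_model
#' @export
read_copula_model <- function(path) {
  kv <- utils::read.table(path, sep = "=", col.names = c("key", "value"),
                          colClasses = "character")
  vals <- stats::setNames(kv$value, kv$key)
  model <- copula_model(vals[["family"]],
                        if (vals[["family"]] == "independence") NULL
                        else as.numeric(vals[["theta"]]))
  if ("n" %in% names(vals)) model$n <- as.integer(vals[["n"]])
  if ("loglik" %in% names(vals)) model$loglik <- as.numeric(vals[["loglik"]])
  model
}
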