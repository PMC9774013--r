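# Hybrid deterministic-stochastic heart-rate forecaster: SSA models and
# extrapolates the trend; Archimedean pair-copulas on the lagged SSA
# residuals predict the stochastic part; their sum is the forecast.

#' Lagged residual matrix with empirical per-column marginals
#'
#' Arranges a residual series into a matrix whose column `j` is the
#' series shifted by `(j - 1) * delay` epochs, so consecutive columns are
#' lag-`delay` copies of each other. Each column carries its empirical
#' marginal: sorted values paired with plotting positions `i / (n + 1)`,
#' giving a piecewise-linear CDF and quantile function (clamped to the
#' observed range outside it).
#'
#' @param residuals Numeric residual series, length at least
#'   `(W - 1) * delay + 2`.
#' @param W Window length (number of columns), default 30.
#' @param delay Epoch delay between consecutive columns, default 1.
#' @return Object of class `"residual_lag_matrix"`: list with the
#'   `matrix` (rows x W), `W`, `delay` and `marginals` (list of sorted
#'   column values).
#' @export
residual_lag_matrix <- function(residuals, W = 30L, delay = 1L) {
  residuals <- as.numeric(residuals)
  W <- as.integer(W); delay <- as.integer(delay)
  stopifnot(W >= 2L, delay >= 1L)
  n <- length(residuals) - (W - 1L) * delay
  if (n < 2L)
    stop(sprintf("residual series too short: need at least %d values for W = %d, delay = %d",
                 (W - 1L) * delay + 2L, W, delay))
  M <- vapply(seq_len(W),
              function(j) residuals[seq_len(n) + (j - 1L) * delay],
              numeric(n))
  structure(list(matrix = M, W = W, delay = delay,
                 marginals = lapply(seq_len(W), function(j) sort(M[, j]))),
            class = "residual_lag_matrix")
}

#' @export
print.residual_lag_matrix <- function(x, ...) {
  cat(sprintf("Residual lag matrix: %d rows x %d columns (delay %d)\n",
              nrow(x$matrix), x$W, x$delay))
  invisible(x)
}

# Empirical marginal CDF of column j at x (plotting positions i/(n+1),
# linear interpolation, clamped). A numerically constant column is
# degenerate: every value maps to probability 1/2.
.marginal_cdf <- function(rlm, j, x) {
  sv <- rlm$marginals[[j]]
  n <- length(sv)
  if (sv[n] - sv[1L] < 1e-12) return(rep(0.5, length(x)))
  stats::approx(sv, seq_len(n) / (n + 1), xout = x, rule = 2,
                ties = "mean")$y
}

# Inverse empirical marginal (quantile) of column j at probability p,
# clamped to the observed range.
.marginal_quantile <- function(rlm, j, p) {
  sv <- rlm$marginals[[j]]
  n <- length(sv)
  if (sv[n] - sv[1L] < 1e-12) return(rep(sv[1L], length(p)))
  stats::approx(seq_len(n) / (n + 1), sv, xout = p, rule = 2,
                ties = "mean")$y
}

#' Fit the hybrid SSA + copula heart-rate forecaster
#'
#' Fits the two-part model on the last `train_length` epochs of `x`:
#' \enumerate{
#'   \item SSA reconstructs the deterministic trend from the first `I`
#'     singular triples of the `L`-window trajectory matrix, and derives
#'     the recurrent linear forecasting coefficients.
#'   \item The residual (observed minus reconstructed) is arranged into a
#'     lagged matrix (window `W`, delay `delay`); per-column empirical
#'     marginals are stored, and for each adjacent column pair an
#'     Archimedean copula is fitted on rank-transformed values — family
#'     selected per pair by Cramer-von-Mises goodness of fit when
#'     `family = "auto"`, or forced to one family otherwise.
#' }
#' A residual series that is numerically zero (the SSA model already
#' explains the signal) degenerates gracefully: all pair-copulas fall
#' back to independence and the forecast equals the SSA forecast.
#'
#' @param x Numeric series (bpm), or a data frame with column `hr_bpm`
#'   as produced by [generate_hr()] / [read_hr_csv()].
#' @param train_length Number of trailing epochs used for fitting
#'   (default 1500).
#' @param L SSA window length (default `floor(train_length / 2)`).
#' @param I Number of SSA components kept as trend (default 60).
#' @param W Residual lag-matrix window (default 30).
#' @param delay Residual lag-matrix delay (default 1).
#' @param horizon Default prediction horizon `H <= W` (default 30).
#' @param n_samples Conditional copula samples averaged per step
#'   (default 3000).
#' @param family `"auto"` (per-pair goodness-of-fit selection) or one of
#'   `"clayton"`, `"frank"`, `"gumbel"`, `"independence"`.
#' @param seed Integer seed governing all stochastic prediction.
#' @param pair_sharing If `TRUE`, fit a single pair-copula on the pooled
#'   lag-`delay` pairs and share it across all steps instead of one
#'   copula per column pair.
#' @param clamp If `TRUE`, forecasts are clamped to `bounds`.
#' @param bounds Physiological amplitude range in bpm (default 25-240).
#' @param verbose Log the selected family and theta per column pair.
#' @return Object of class `"ssacop"`.
#' @seealso [predict.ssacop()], [evaluate_horizon()]
#' @export
#' @examples
#' hr <- generate_hr(default_running_profile(), seed = 7)
#' fit <- ssacop(hr, train_length = 300, L = 150, I = 10,
#'               n_samples = 200, family = "frank", seed = 1)
#' fit
#' predict(fit, h = 5)
ssacop <- function(x, train_length = 1500L, L = NULL, I = 60L, W = 30L,
                   delay = 1L, horizon = 30L, n_samples = 3000L,
                   family = c("auto", "clayton", "frank", "gumbel",
                              "independence"),
                   seed = 1L, pair_sharing = FALSE, clamp = FALSE,
                   bounds = c(25, 240), verbose = FALSE) {
  family <- match.arg(family)
  if (is.data.frame(x)) {
    if (!"hr_bpm" %in% names(x))
      stop("data frame input must have an `hr_bpm` column")
    x <- x$hr_bpm
  }
  x <- as.numeric(x)
  train_length <- as.integer(train_length)
  if (is.null(L)) L <- train_length %/% 2L
  L <- as.integer(L); I <- as.integer(I); W <- as.integer(W)
  delay <- as.integer(delay); horizon <- as.integer(horizon)
  n_samples <- as.integer(n_samples)
  if (length(x) < train_length)
    stop(sprintf("series length %d < train_length %d", length(x), train_length))
  if (!(train_length > L && L > I && I >= 1L))
    stop("config must satisfy train_length > L > I >= 1")
  if (horizon > W) stop("`horizon` must not exceed the residual window `W`")
  if (n_samples < 1L) stop("`n_samples` must be >= 1")
  if (length(bounds) != 2L || bounds[1L] >= bounds[2L])
    stop("`bounds` must be an ordered pair")

  y <- utils::tail(x, train_length)
  ssa <- .ssa_train(y, L, I)
  if (is.null(ssa$coef))
    stop("degenerate SSA recurrence (verticality >= 1); cannot forecast")
  resid <- y - ssa$recon
  rlm <- residual_lag_matrix(resid, W, delay)

  degenerate <- max(abs(resid)) < 1e-6
  n_pairs <- if (pair_sharing) 1L else W - 1L
  fit_pair <- function(a, b) {
    if (degenerate || stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
      return(list(model = copula_model("independence"), gof = NULL))
    u <- rank_transform(a); v <- rank_transform(b)
    if (family == "auto") {
      gof <- select_copula(u, v)
      list(model = gof$selected, gof = gof$table)
    } else if (family == "independence") {
      list(model = copula_model("independence"), gof = NULL)
    } else {
      list(model = tryCatch(fit_copula(u, v, family),
                            error = function(e) {
                              warning("copula fit failed (", conditionMessage(e),
                                      "); using independence")
                              copula_model("independence")
                            }),
           gof = NULL)
    }
  }
  pairs <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    if (pair_sharing) {
      # pooled lag-`delay` pairs over the whole residual series
      a <- resid[seq_len(length(resid) - delay)]
      b <- resid[seq_len(length(resid) - delay) + delay]
    } else {
      a <- rlm$matrix[, j]; b <- rlm$matrix[, j + 1L]
    }
    pairs[[j]] <- fit_pair(a, b)
    if (verbose) {
      m <- pairs[[j]]$model
      message(sprintf("pair %d: %s theta = %s", j, m$family,
                      format(m$theta, digits = 4)))
    }
  }

  structure(
    list(ssa = ssa, residuals = resid, rlm = rlm, pairs = pairs,
         config = list(train_length = train_length, L = L, I = I, W = W,
                       delay = delay, horizon = horizon,
                       n_samples = n_samples, family = family, seed = seed,
                       pair_sharing = pair_sharing, clamp = clamp,
                       bounds = bounds),
         degenerate = degenerate,
         train = y,
         call = match.call()),
    class = "ssacop")
}

#' @export
print.ssacop <- function(x, ...) {
  cfg <- x$config
  cat("Hybrid SSA + copula heart-rate forecaster\n")
  cat(sprintf("  training epochs: %d, SSA window L = %d, components I = %d\n",
              cfg$train_length, cfg$L, cfg$I))
  cat(sprintf("  residual lag matrix: window %d, delay %d; %d pair-copula(s)\n",
              cfg$W, cfg$delay, length(x$pairs)))
  fams <- vapply(x$pairs, function(p) p$model$family, character(1))
  cat("  pair families:", paste(names(table(fams)),
                                table(fams), sep = ":", collapse = ", "), "\n")
  cat(sprintf("  residual sd: %.3f bpm; seed %d\n",
              stats::sd(x$residuals), cfg$seed))
  invisible(x)
}

#' @export
summary.ssacop <- function(object, ...) {
  thetas <- vapply(object$pairs, function(p) {
    th <- p$model$theta
    if (is.null(th)) NA_real_ else th
  }, numeric(1))
  fams <- vapply(object$pairs, function(p) p$model$family, character(1))
  out <- list(config = object$config,
              pair_table = data.frame(pair = seq_along(fams),
                                      family = fams, theta = thetas),
              residual_sd = stats::sd(object$residuals),
              ssa_energy = object$ssa$decomp$values^2 /
                sum(object$ssa$decomp$values^2))
  class(out) <- "summary.ssacop"
  out
}

#' @export
print.summary.ssacop <- function(x, ...) {
  cat("Hybrid SSA + copula forecaster - summary\n\n")
  cat(sprintf("Leading singular-value energy shares: %s\n",
              paste(signif(utils::head(x$ssa_energy, 5L), 3L), collapse = ", ")))
  cat(sprintf("Residual sd: %.3f bpm\n\n", x$residual_sd))
  cat("Pair-copulas:\n")
  print(x$pair_table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ssacop <- function(object, ...) {
  stats::setNames(
    vapply(object$pairs, function(p)
      if (is.null(p$model$theta)) NA_real_ else p$model$theta, numeric(1)),
    paste0("theta_", seq_along(object$pairs)))
}

#' @export
residuals.ssacop <- function(object, ...) object$residuals

#' @export
fitted.ssacop <- function(object, ...) object$ssa$recon

# One-step-chained conditional residual forecast. The conditioning value
# starts at the last observed training residual; each step's predicted
# mean becomes the next step's conditioning value. Step h uses the copula
# of column pair min(h, W - 1), mapping through column j's marginal into
# rank space and back through column j + 1's inverse marginal.
.predict_anomaly <- function(model, h, n_samples, seed) {
  if (model$degenerate) return(numeric(h))
  rlm <- model$rlm
  W <- model$config$W
  z <- model$residuals[length(model$residuals)]
  out <- numeric(h)
  with_seed(seed, {
    for (step in seq_len(h)) {
      j <- min(step, W - 1L)
      pair <- model$pairs[[if (model$config$pair_sharing) 1L else j]]
      n_m <- length(rlm$marginals[[j]])
      u <- .marginal_cdf(rlm, j, z)
      u <- min(max(u, 1 / (n_m + 1)), n_m / (n_m + 1))
      w <- stats::runif(n_samples)
      v <- .conditional_quantile(pair$model, w, u)
      out[step] <- mean(.marginal_quantile(rlm, j + 1L, v))
      z <- out[step]
    }
  })
  out
}

#' Forecast heart rate from a fitted hybrid model
#'
#' Produces the `h`-step-ahead forecast as the sum of a deterministic and
#' a stochastic part. The deterministic part continues the SSA
#' reconstruction with the recurrent linear formula. The stochastic part
#' chains one-step conditional copula predictions: the latest residual
#' (observed at step 1, predicted thereafter) is mapped to rank space
#' through the current column's empirical marginal, `n_samples` draws are
#' taken from the pair-copula's conditional CDF, each is back-transformed
#' through the next column's inverse marginal, and their mean is the
#' predicted residual. The two parts always add exactly:
#' `type = "hybrid"` equals `"trend"` plus `"anomaly"` element-wise.
#'
#' @param object A fitted [ssacop()] model.
#' @param h Forecast horizon; must not exceed the residual window `W`.
#' @param type Which component to return (all are computed under the same
#'   RNG stream, so components are consistent across calls with the same
#'   seed).
#' @param seed Seed for the conditional sampling (default: the model's).
#' @param clamp Clamp the forecast to the model's amplitude bounds
#'   (default: the model's setting).
#' @param ... Unused.
#' @return Numeric vector of length `h` (bpm for `"hybrid"`/`"trend"`).
#' @export
predict.ssacop <- function(object, h = object$config$horizon,
                           type = c("hybrid", "trend", "anomaly"),
                           seed = object$config$seed,
                           clamp = object$config$clamp, ...) {
  type <- match.arg(type)
  h <- as.integer(h)
  if (h < 1L) stop("`h` must be >= 1")
  if (h > object$config$W)
    stop(sprintf("`h` = %d exceeds the residual window W = %d", h,
                 object$config$W))
  trend <- .lrr_continue(object$ssa$recon, object$ssa$coef, h)
  anom <- .predict_anomaly(object, h, object$config$n_samples, seed)
  out <- switch(type, hybrid = trend + anom, trend = trend, anomaly = anom)
  if (clamp && type != "anomaly")
    out <- pmin(pmax(out, object$config$bounds[1L]), object$config$bounds[2L])
  out
}

#' Simulate conditional residual sample paths from a fitted model
#'
#' Draws `nsim` stochastic residual trajectories of length `h` by the
#' same chained conditional-copula mechanism as [predict.ssacop()], but
#' propagating a sampled value (not the mean) at each step. Useful for
#' visualising forecast uncertainty of the anomaly part.
#'
#' @param object A fitted [ssacop()] model.
#' @param nsim Number of trajectories.
#' @param seed Integer seed.
#' @param h Horizon (default the model's).
#' @param ... Unused.
#' @return An `h x nsim` matrix of residual paths (bpm).
#' @export
simulate.ssacop <- function(object, nsim = 1, seed = object$config$seed,
                            h = object$config$horizon, ...) {
  rlm <- object$rlm
  W <- object$config$W
  with_seed(seed, {
    vapply(seq_len(nsim), function(k) {
      z <- object$residuals[length(object$residuals)]
      path <- numeric(h)
      for (step in seq_len(h)) {
        j <- min(step, W - 1L)
        pair <- object$pairs[[if (object$config$pair_sharing) 1L else j]]
        n_m <- length(rlm$marginals[[j]])
        u <- .marginal_cdf(rlm, j, z)
        u <- min(max(u, 1 / (n_m + 1)), n_m / (n_m + 1))
        v <- .conditional_quantile(pair$model, stats::runif(1), u)
        z <- .marginal_quantile(rlm, j + 1L, v)
        path[step] <- z
      }
      path
    }, numeric(h))
  })
}

#' @export
plot.ssacop <- function(x, h = x$config$horizon, ...) {
  n <- length(x$train)
  fc <- predict(x, h = h)
  graphics::plot(seq_len(n), x$train, type = "l", col = "grey40",
                 xlab = "epoch (s)", ylab = "heart rate (bpm)",
                 xlim = c(1, n + h), ...)
  graphics::lines(seq_len(n), x$ssa$recon, col = "blue")
  graphics::lines(n + seq_len(h), fc, col = "red", lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = c(1, 1, 2),
                   col = c("grey40", "blue", "red"),
                   legend = c("observed", "SSA reconstruction", "hybrid forecast"))
  invisible(x)
}

#' Sliding-origin evaluation: mean absolute error per forecast horizon
#'
#' Slides a prediction origin across the series: at each origin the model
#' is fitted on the preceding `train_length` epochs, an `H`-step forecast
#' is issued, and the absolute error against the actually observed values
#' is recorded per horizon step. Errors are averaged over origins into a
#' per-step MAE table; the SSA-only (deterministic part alone) errors are
#' recorded alongside as the natural baseline.
#'
#' Each origin's conditional sampling is seeded deterministically from
#' `seed` and the origin index, so the whole table is reproducible
#' bit-for-bit.
#'
#' @inheritParams ssacop
#' @param H Forecast horizon evaluated at each origin.
#' @param slide_step Origin increment in epochs (default 1).
#' @param max_origins Cap on the number of origins (default all).
#' @param refit_every Refit the SSA decomposition and the pair-copulas at
#'   every `refit_every`-th origin; in between, the previous signal
#'   subspace (left singular vectors), recurrence coefficients and
#'   copulas are reused on the new window, trading fidelity for speed.
#' @param ... Further arguments passed to [ssacop()] (e.g. `family`,
#'   `n_samples`, `pair_sharing`).
#' @return Object of class `"horizon_mae"`: list with `table`
#'   (data frame `step`, `mae_bpm`, `mae_ssa_bpm`, `n_origins`), `errors`
#'   and `errors_ssa` (origins x H matrices of absolute errors), and
#'   `origins` (the origin epochs).
#' @export
evaluate_horizon <- function(x, train_length = 1500L, H = 30L,
                             slide_step = 1L, max_origins = NULL,
                             refit_every = 1L, seed = 1L, verbose = FALSE,
                             ...) {
  if (is.data.frame(x)) x <- x$hr_bpm
  x <- as.numeric(x)
  N <- length(x)
  train_length <- as.integer(train_length)
  H <- as.integer(H)
  if (N < train_length + H + 1L)
    stop(sprintf("series length %d < train_length + H + 1 = %d", N,
                 train_length + H + 1L))
  origins <- seq.int(train_length, N - H, by = as.integer(slide_step))
  if (!is.null(max_origins)) origins <- utils::head(origins, max_origins)
  n_o <- length(origins)
  errs <- matrix(NA_real_, n_o, H)
  errs_ssa <- matrix(NA_real_, n_o, H)
  model <- NULL
  for (k in seq_len(n_o)) {
    o <- origins[k]
    win <- x[(o - train_length + 1L):o]
    origin_seed <- (seed + o) %% 2147483647L
    if (k == 1L || (k - 1L) %% refit_every == 0L) {
      model <- ssacop(win, train_length = train_length, horizon = H,
                      seed = origin_seed, ...)
    } else {
      model <- .refit_frozen(model, win, origin_seed)
    }
    trend <- .lrr_continue(model$ssa$recon, model$ssa$coef, H)
    anom <- .predict_anomaly(model, H, model$config$n_samples, origin_seed)
    actual <- x[o + seq_len(H)]
    errs[k, ] <- abs(trend + anom - actual)
    errs_ssa[k, ] <- abs(trend - actual)
    if (verbose && k %% 25L == 0L)
      message(sprintf("origin %d/%d", k, n_o))
  }
  structure(
    list(table = data.frame(step = seq_len(H),
                            mae_bpm = colMeans(errs),
                            mae_ssa_bpm = colMeans(errs_ssa),
                            n_origins = n_o),
         errors = errs, errors_ssa = errs_ssa, origins = origins,
         seed = seed),
    class = "horizon_mae")
}

# Re-estimate the SSA reconstruction on a new window by projecting its
# trajectory matrix onto the frozen signal subspace; copulas, marginals
# and recurrence coefficients are reused from the last full fit.
.refit_frozen <- function(model, win, origin_seed) {
  cfg <- model$config
  ssa <- .ssa_train(win, cfg$L, cfg$I, basis = model$ssa$U)
  ssa$coef <- model$ssa$coef
  model$ssa <- ssa
  model$residuals <- win - ssa$recon
  model$train <- win
  model$config$seed <- origin_seed
  model
}

#' @export
print.horizon_mae <- function(x, ...) {
  cat(sprintf("Sliding-origin forecast evaluation over %d origins\n",
              x$table$n_origins[1L]))
  cat(sprintf("  step 1  MAE: %.3f bpm (SSA-only %.3f)\n",
              x$table$mae_bpm[1L], x$table$mae_ssa_bpm[1L]))
  H <- nrow(x$table)
  cat(sprintf("  step %d MAE: %.3f bpm (SSA-only %.3f)\n",
              H, x$table$mae_bpm[H], x$table$mae_ssa_bpm[H]))
  invisible(x)
}

#' @export
plot.horizon_mae <- function(x, ...) {
  graphics::plot(x$table$step, x$table$mae_bpm, type = "b", pch = 16,
                 col = "darkgreen", xlab = "prediction step (s)",
                 ylab = "MAE (bpm)",
                 ylim = range(0, x$table$mae_bpm, x$table$mae_ssa_bpm), ...)
  graphics::lines(x$table$step, x$table$mae_ssa_bpm, type = "b", pch = 1,
                  col = "grey40")
  graphics::legend("topleft", bty = "n", pch = c(16, 1),
                   col = c("darkgreen", "grey40"),
                   legend = c("hybrid (SSA + copula)", "SSA only"))
  invisible(x)
}

#' Write a horizon-MAE table as CSV
#'
#' Columns: `step`, `mae_bpm`, `n_origins` (plus `mae_ssa_bpm` when the
#' SSA-only baseline is present).
#'
#' @param x A `"horizon_mae"` object from [evaluate_horizon()].
#' @param path Output file path.
#' @export
write_horizon_csv <- function(x, path) {
  stopifnot(inherits(x, "horizon_mae"))
  tab <- x$table[, c("step", "mae_bpm", "n_origins",
                     intersect("mae_ssa_bpm", names(x$table)))]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
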