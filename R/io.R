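# CSV input/output and the end-to-end pipeline runner.

#' Read a heart-rate series from CSV
#'
#' Expects a header and two numeric columns: time in seconds and heart
#' rate in bpm (any column names; the first two columns are used).
#' Validates that timestamps are strictly increasing and uniformly
#' spaced within tolerance `1e-6` s, reporting the offending line number
#' otherwise.
#'
#' @param path CSV file path.
#' @return Data frame with columns `t_seconds`, `hr_bpm`.
#' @export
read_hr_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (ncol(df) < 2L)
    stop("expected two columns (time seconds, hr bpm) in ", path)
  tt <- suppressWarnings(as.numeric(df[[1L]]))
  hr <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(!is.finite(tt) | !is.finite(hr))
  if (length(bad))
    stop(sprintf("non-numeric cell at line %d of %s", bad[1L] + 1L, path))
  d <- diff(tt)
  nonmono <- which(d <= 0)
  if (length(nonmono))
    stop(sprintf("non-monotone or duplicated timestamp at line %d of %s",
                 nonmono[1L] + 2L, path))
  if (length(d) > 1L) {
    irregular <- which(abs(d - d[1L]) > 1e-6)
    if (length(irregular))
      stop(sprintf("irregular sampling at line %d of %s (interval %g, expected %g)",
                   irregular[1L] + 2L, path, d[irregular[1L]], d[1L]))
  }
  data.frame(t_seconds = tt, hr_bpm = hr)
}

#' Write a heart-rate series to CSV
#'
#' @param x Data frame with columns `t_seconds`, `hr_bpm` (as returned
#'   by [generate_hr()] or [read_hr_csv()]), or a numeric vector (1 Hz
#'   timestamps are generated).
#' @param path Output file path.
#' @export
write_hr_csv <- function(x, path) {
  if (!is.data.frame(x))
    x <- data.frame(t_seconds = seq_along(x), hr_bpm = as.numeric(x))
  stopifnot(all(c("t_seconds", "hr_bpm") %in% names(x)))
  utils::write.csv(x[, c("t_seconds", "hr_bpm")], path, row.names = FALSE)
  invisible(path)
}

# 32-bit FNV-1a hash of a character vector, as an 8-digit hex string;
# used only to stamp artifacts with the configuration they came from.
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- (as.numeric(bitwAnd(h, -1L) %% 2^32) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full modelling and evaluation pipeline
#'
#' Fits the hybrid model, issues a forecast, runs the sliding-origin
#' evaluation and writes all artifacts to `outdir`:
#' `reconstructed.csv` (series + SSA trend), `residuals.csv`,
#' `forecast.csv` (trend, anomaly and hybrid per step),
#' `horizon_mae.csv`, `abs_errors.csv` (origins x steps matrix of
#' absolute errors), `mae_plot.png` and `manifest.txt` (seed, full
#' configuration, config hash, package and R versions). Numeric outputs
#' are bit-reproducible for a fixed input and seed.
#'
#' @param input Path to an input CSV, or `NULL` to generate a synthetic
#'   series from `profile`.
#' @param outdir Output directory (created if missing).
#' @param profile Synthetic protocol profile used when `input` is `NULL`.
#' @param seed Integer seed for generation and prediction.
#' @param train_length,L,I,W,delay,horizon,n_samples,family,pair_sharing
#'   Passed to [ssacop()] / [evaluate_horizon()].
#' @param max_origins Cap on evaluation origins (keeps runtime bounded).
#' @param refit_every Refit cadence for the evaluation (see
#'   [evaluate_horizon()]).
#' @param verbose Log progress and per-pair copula choices.
#' @return Invisibly, a list with the fitted model, forecast and
#'   evaluation object.
#' @export
run_pipeline <- function(input = NULL, outdir,
                         profile = default_running_profile(),
                         seed = 1L, train_length = 1500L, L = NULL,
                         I = 60L, W = 30L, delay = 1L, horizon = 30L,
                         n_samples = 3000L, family = "auto",
                         pair_sharing = FALSE, max_origins = NULL,
                         refit_every = 1L, verbose = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  series <- if (is.null(input)) generate_hr(profile, seed = seed)
            else read_hr_csv(input)
  model <- ssacop(series, train_length = train_length, L = L, I = I, W = W,
                  delay = delay, horizon = horizon, n_samples = n_samples,
                  family = family, seed = seed, pair_sharing = pair_sharing,
                  verbose = verbose)
  for (j in seq_along(model$pairs)) {
    m <- model$pairs[[j]]$model
    if (verbose)
      message(sprintf("selected pair %d: %s (theta = %s)", j, m$family,
                      format(m$theta, digits = 4)))
  }
  n_train <- model$config$train_length
  t_train <- utils::tail(series$t_seconds, n_train)
  utils::write.csv(data.frame(t_seconds = t_train, hr_bpm = model$train,
                              trend_bpm = fitted(model)),
                   file.path(outdir, "reconstructed.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t_seconds = t_train,
                              residual_bpm = residuals(model)),
                   file.path(outdir, "residuals.csv"), row.names = FALSE)
  fc_trend <- predict(model, type = "trend")
  fc_anom <- predict(model, type = "anomaly")
  dt <- if (nrow(series) > 1L) diff(series$t_seconds[1:2]) else 1
  utils::write.csv(data.frame(step = seq_len(horizon),
                              t_seconds = max(series$t_seconds) +
                                dt * seq_len(horizon),
                              trend_bpm = fc_trend,
                              anomaly_bpm = fc_anom,
                              hr_pred_bpm = fc_trend + fc_anom),
                   file.path(outdir, "forecast.csv"), row.names = FALSE)
  ev <- evaluate_horizon(series, train_length = train_length, H = horizon,
                         max_origins = max_origins,
                         refit_every = refit_every, seed = seed,
                         L = L, I = I, W = W, delay = delay,
                         n_samples = n_samples, family = family,
                         pair_sharing = pair_sharing, verbose = verbose)
  write_horizon_csv(ev, file.path(outdir, "horizon_mae.csv"))
  errdf <- as.data.frame(ev$errors)
  names(errdf) <- paste0("step_", seq_len(ncol(errdf)))
  utils::write.csv(cbind(origin = ev$origins, errdf),
                   file.path(outdir, "abs_errors.csv"), row.names = FALSE)
  grDevices::png(file.path(outdir, "mae_plot.png"), width = 800, height = 500)
  plot(ev)
  grDevices::dev.off()
  cfg <- model$config
  cfg_lines <- c(paste0("input=", if (is.null(input)) "synthetic" else input),
                 paste0(names(cfg), "=",
                        vapply(cfg, function(x) paste(x, collapse = ","),
                               character(1))))
  manifest <- c(cfg_lines,
                paste0("config_hash=", .config_hash(cfg_lines)),
                paste0("package_version=",
                       as.character(utils::packageVersion("ssacop"))),
                paste0("r_version=", R.version.string))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(list(model = model, forecast = fc_trend + fc_anom,
                 evaluation = ev))
}
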