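# Seeded generator of protocol-style running heart-rate series: piecewise
# plateau targets smoothed by a first-order physiological response, plus
# optional periodic components and serially dependent noise.

#' Default four-phase running protocol profile
#'
#' Returns the profile of a running session with four phases — initial
#' flat, uphill, downhill, final flat — with phase boundaries at
#' 465 s, 1112 s, 1547 s and total duration 2634 s at 1 Hz sampling.
#' Plateau heart-rate targets (90 / 165 / 150 / 155 bpm), the 30 s
#' response time-constant and the small periodic component are
#' documented generator constants chosen as physiologically plausible;
#' they are properties of this synthetic profile, not of any particular
#' recorded subject.
#'
#' @param plateaus Target plateau HR per phase (bpm).
#' @param durations Phase durations in seconds.
#' @param tau First-order response time-constant in seconds: after a
#'   change of load the modelled HR approaches the new plateau like
#'   `1 - exp(-t / tau)`.
#' @param periodic List of periodic components, each `c(amplitude =, period =)`
#'   in bpm and seconds.
#' @param noise Noise model: `list(model = "white", sigma =)`,
#'   `list(model = "ar1", phi =, sigma =)` (sigma = innovation sd) or
#'   `list(model = "copula", family =, theta =, sigma =)` (Gaussian
#'   marginal of sd sigma, dependence chained through the copula's
#'   conditional distribution).
#' @param bounds Amplitude range the signal is clipped to (bpm).
#' @param sampling Sampling interval in seconds (default 1).
#' @return Object of class `"hr_profile"`.
#' @export
#' @examples
#' prof <- default_running_profile()
#' sum(prof$durations)  # 2634 s
default_running_profile <- function(plateaus = c(flat_initial = 90,
                                                 uphill = 165,
                                                 downhill = 150,
                                                 flat_final = 155),
                                    durations = c(465, 647, 435, 1087),
                                    tau = 30,
                                    periodic = list(c(amplitude = 3,
                                                      period = 300)),
                                    noise = list(model = "ar1", phi = 0.8,
                                                 sigma = 2),
                                    bounds = c(25, 240),
                                    sampling = 1) {
  profile <- structure(list(plateaus = plateaus, durations = durations,
                            tau = tau, periodic = periodic, noise = noise,
                            bounds = bounds, sampling = sampling),
                       class = "hr_profile")
  validate_profile(profile)
  profile
}

#' Validate an HR protocol profile
#'
#' Checks field types, positivity of durations and tau, ordering of the
#' amplitude bounds, noise-model parameters (`sigma >= 0`, `phi` in
#' (-1, 1), copula parameter in its family domain). All failures are
#' reported together.
#'
#' @param profile An `"hr_profile"` object.
#' @return The profile, invisibly; errors with the list of failures
#'   otherwise.
#' @export
validate_profile <- function(profile) {
  fails <- character(0)
  add <- function(msg) fails <<- c(fails, msg)
  if (length(profile$plateaus) != length(profile$durations))
    add("plateaus and durations must have equal length")
  if (any(profile$durations <= 0)) add("all phase durations must be > 0")
  if (!isTRUE(profile$tau > 0)) add("tau must be > 0")
  if (!isTRUE(profile$sampling > 0)) add("sampling interval must be > 0")
  if (length(profile$bounds) != 2L || profile$bounds[1L] >= profile$bounds[2L])
    add("bounds must be an ordered pair")
  nm <- profile$noise$model
  if (!nm %in% c("white", "ar1", "copula"))
    add("noise model must be one of white, ar1, copula")
  if (!is.null(profile$noise$sigma) && profile$noise$sigma < 0)
    add("noise sigma must be >= 0")
  if (identical(nm, "ar1") &&
      !(is.numeric(profile$noise$phi) && abs(profile$noise$phi) < 1))
    add("ar1 phi must lie in (-1, 1)")
  if (identical(nm, "copula")) {
    ok <- tryCatch({
      copula_model(profile$noise$family, profile$noise$theta); TRUE
    }, error = function(e) FALSE)
    if (!ok) add("copula noise family/theta invalid")
  }
  for (p in profile$periodic)
    if (!all(c("amplitude", "period") %in% names(p)) || p[["period"]] <= 0)
      add("each periodic component needs amplitude and period > 0")
  if (length(fails))
    stop("invalid profile:\n  - ", paste(fails, collapse = "\n  - "))
  invisible(profile)
}

#' @export
print.hr_profile <- function(x, ...) {
  cat("HR protocol profile:", length(x$plateaus), "phases,",
      sum(x$durations), "s at", 1 / x$sampling, "Hz\n")
  tab <- data.frame(phase = names(x$plateaus), duration_s = x$durations,
                    plateau_bpm = unname(x$plateaus))
  print(tab, row.names = FALSE)
  cat(sprintf("tau = %g s; noise model: %s\n", x$tau, x$noise$model))
  invisible(x)
}

# Noise-free smoothed trend of a profile (first-order response to the
# piecewise plateau target, plus periodic components), before clipping.
.profile_trend <- function(profile) {
  dt <- profile$sampling
  n_steps <- round(profile$durations / dt)
  target <- rep(unname(profile$plateaus), times = n_steps)
  n <- length(target)
  g <- numeric(n)
  level <- unname(profile$plateaus[1L])
  a <- dt / profile$tau
  for (t in seq_len(n)) {
    level <- level + a * (target[t] - level)
    g[t] <- level
  }
  tt <- seq_len(n) * dt
  for (p in profile$periodic)
    g <- g + p[["amplitude"]] * sin(2 * pi * tt / p[["period"]])
  g
}

#' Generate a synthetic heart-rate series from a protocol profile
#'
#' Produces a series of length `sum(durations) / sampling`: the plateau
#' targets smoothed by a first-order exponential response with
#' time-constant `tau` (emulating the delayed physiological reaction to a
#' change of load), plus periodic components, plus noise drawn from the
#' profile's noise model, clipped to the amplitude bounds. Deterministic
#' for a fixed seed: the trend does not depend on the seed at all, only
#' the noise does.
#'
#' @param profile An `"hr_profile"`, e.g. [default_running_profile()].
#' @param seed Integer seed for the noise.
#' @return A data frame with columns `t_seconds` and `hr_bpm`, carrying
#'   the noise-free trend as attribute `"trend"`.
#' @export
#' @examples
#' hr <- generate_hr(default_running_profile(), seed = 1)
#' nrow(hr)           # 2634
#' range(hr$hr_bpm)   # within [25, 240]
generate_hr <- function(profile = default_running_profile(), seed = NULL) {
  validate_profile(profile)
  trend <- .profile_trend(profile)
  n <- length(trend)
  sigma <- profile$noise$sigma
  noise <- if (is.null(sigma) || sigma == 0) {
    numeric(n)
  } else {
    switch(profile$noise$model,
      white = with_seed(seed, stats::rnorm(n, 0, sigma)),
      ar1 = with_seed(seed, {
        phi <- profile$noise$phi
        innov <- stats::rnorm(n, 0, sigma)
        init <- stats::rnorm(1, 0, sigma / sqrt(1 - phi^2))
        as.numeric(stats::filter(innov, phi, method = "recursive",
                                 init = init))
      }),
      copula = with_seed(seed, {
        cop <- copula_model(profile$noise$family, profile$noise$theta)
        u <- numeric(n)
        u[1L] <- stats::runif(1)
        for (t in 2L:n)
          u[t] <- .conditional_quantile(cop, stats::runif(1), u[t - 1L])
        stats::qnorm(u, 0, sigma)
      }))
  }
  hr <- pmin(pmax(trend + noise, profile$bounds[1L]), profile$bounds[2L])
  out <- data.frame(t_seconds = seq_len(n) * profile$sampling, hr_bpm = hr)
  attr(out, "trend") <- trend
  out
}
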