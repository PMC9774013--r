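test_that("residual lag matrix has the shift structure and invertible marginals", {
  rlm <- residual_lag_matrix(1:5, W = 3, delay = 1)
  expect_identical(rlm$matrix,
                   matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 3, 3))
  expect_identical(ncol(rlm$matrix), 3L)

  set.seed(1)
  res <- rnorm(200)
  rlm <- residual_lag_matrix(res, W = 30, delay = 1)
  expect_identical(ncol(rlm$matrix), 30L)
  # column j+1 is column j shifted by the delay
  for (j in 1:29)
    expect_identical(rlm$matrix[-nrow(rlm$matrix), j + 1],
                     rlm$matrix[-1, j])
  # marginal quantile inverts the marginal CDF at interior sample points
  x <- rlm$matrix[5:150, 7]
  p <- ssacop:::.marginal_cdf(rlm, 7, x)
  expect_lt(max(abs(ssacop:::.marginal_quantile(rlm, 7, p) - x)), 1e-9)

  expect_error(residual_lag_matrix(1:10, W = 30), "too short")
})

test_that("fitting a noiseless low-rank signal degenerates to the SSA model", {
  t <- 1:400
  x <- 100 + 5 * sin(2 * pi * t / 60) + 2 * sin(2 * pi * t / 23)
  fit <- ssacop(x, train_length = 400, L = 100, I = 5, W = 30,
                n_samples = 50, seed = 3)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_true(all(vapply(fit$pairs, function(p) p$model$family,
                         character(1)) == "independence"))
  expect_identical(predict(fit, h = 10), predict(fit, h = 10, type = "trend"))
  expect_identical(length(fit$pairs), 29L)      # W - 1 pair models
  expect_identical(fit$config$seed, 3)          # provenance
})

test_that("hybrid forecast is additive, seeded and clampable", {
  hr <- generate_hr(default_running_profile(), seed = 5)
  fit <- ssacop(hr, train_length = 300, L = 150, I = 10, n_samples = 200,
                family = "frank", seed = 2, pair_sharing = TRUE)
  p1 <- predict(fit, h = 30)
  p2 <- predict(fit, h = 30)
  expect_identical(p1, p2)  # same seed, bit-identical
  expect_equal(p1, predict(fit, h = 30, type = "trend") +
                 predict(fit, h = 30, type = "anomaly"),
               tolerance = 1e-12)
  pc <- predict(fit, h = 30, clamp = TRUE)
  expect_true(all(pc >= 25 & pc <= 240))
  expect_error(predict(fit, h = 31), "residual window")
  expect_length(predict(fit, h = 1), 1L)

  expect_named(coef(fit), "theta_1")
  expect_identical(length(fitted(fit)), 300L)
  sims <- simulate(fit, nsim = 4, seed = 9, h = 10)
  expect_identical(dim(sims), c(10L, 4L))
  expect_identical(sims, simulate(fit, nsim = 4, seed = 9, h = 10))
})

test_that("sliding-origin evaluation produces finite, reproducible MAE tables", {
  # a signal the SSA model forecasts essentially perfectly: near-zero MAE
  x <- 100 + 10 * sin(2 * pi * (1:400) / 40)
  ev0 <- evaluate_horizon(x, train_length = 300, H = 10, max_origins = 5,
                          L = 100, I = 3, W = 12, n_samples = 20, seed = 1)
  expect_lt(max(ev0$table$mae_bpm), 1e-4)

  hr <- generate_hr(default_running_profile(), seed = 6)
  ev <- evaluate_horizon(hr, train_length = 300, H = 30, max_origins = 8,
                         L = 150, I = 10, n_samples = 100, family = "frank",
                         pair_sharing = TRUE, seed = 4)
  expect_identical(nrow(ev$table), 30L)
  expect_true(all(is.finite(ev$table$mae_bpm)))
  expect_true(all(ev$table$mae_bpm >= 0))
  expect_identical(ev$table$n_origins[1], 8L)
  ev2 <- evaluate_horizon(hr, train_length = 300, H = 30, max_origins = 8,
                          L = 150, I = 10, n_samples = 100, family = "frank",
                          pair_sharing = TRUE, seed = 4)
  expect_identical(ev$table, ev2$table)

  # frozen-basis refitting also runs and stays finite
  ev3 <- evaluate_horizon(hr, train_length = 300, H = 10, max_origins = 6,
                          refit_every = 3, L = 150, I = 10, n_samples = 50,
                          family = "frank", pair_sharing = TRUE, seed = 4)
  expect_true(all(is.finite(ev3$table$mae_bpm)))

  expect_error(evaluate_horizon(hr$hr_bpm[1:100], train_length = 300, H = 30),
               "train_length")
})
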