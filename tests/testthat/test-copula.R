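test_that("rank transform maps to (0,1), averages ties and ignores monotone maps", {
  expect_equal(rank_transform(c(10, 20, 30)), c(0.25, 0.5, 0.75))
  expect_equal(rank_transform(c(5, 5)), c(0.5, 0.5))
  set.seed(1)
  x <- rnorm(50)
  expect_identical(rank_transform(x), rank_transform(exp(x)))
  expect_identical(rank_transform(x), rank_transform(x^3))
  expect_true(all(rank_transform(x) > 0 & rank_transform(x) < 1))
  expect_error(rank_transform(1), "length")
})

test_that("empirical copula counts pairs and matches brute force exhaustively", {
  expect_equal(empirical_copula(0.5, 0.5, 0.5, 0.5), 1)
  expect_equal(empirical_copula(0.5, 0.5, 0.4, 0.5), 0)

  # comonotone sample of n = 4: C_e(k/5, k/5) = k/4
  u <- (1:4) / 5
  expect_equal(empirical_copula(u, u, u, u), (1:4) / 4)

  set.seed(2)
  for (n in 2:12) {
    u <- rank_transform(rnorm(n)); v <- rank_transform(rnorm(n))
    pts <- cbind(runif(15), runif(15))
    got <- empirical_copula(u, v, pts[, 1], pts[, 2])
    want <- vapply(1:15, function(k)
      brute_empirical_copula(u, v, pts[k, 1], pts[k, 2]), numeric(1))
    expect_identical(got, want)
    expect_equal(empirical_copula(u, v, 1, 1), 1)
  }

  # monotone invariance via the rank transform
  x <- rnorm(40); y <- rnorm(40)
  expect_identical(
    empirical_copula(rank_transform(x), rank_transform(y), 0.3, 0.8),
    empirical_copula(rank_transform(exp(x)), rank_transform(atan(y)), 0.3, 0.8))
})

test_that("generators vanish at 1 and decrease on (0,1]", {
  expect_equal(copula_generator("clayton", 1, 0.5), 1)
  expect_equal(copula_generator("gumbel", 3.7, 1), 0)
  expect_equal(copula_generator("frank", 1, 1), 0)
  tt <- seq(0.05, 1, length.out = 40)
  for (fam in c("clayton", "frank", "gumbel")) {
    th <- c(clayton = 2, frank = 4, gumbel = 2)[[fam]]
    phi <- copula_generator(fam, th, tt)
    expect_true(all(phi >= 0))
    expect_true(all(diff(phi) <= 0))
    expect_equal(phi[length(phi)], 0)
  }
  expect_error(copula_generator("gumbel", 0.5, 0.5), "domain")
})

test_that("copula CDFs match closed forms, margins and 2-increasingness", {
  expect_equal(copula_cdf(copula_model("clayton", 2), 0.5, 0.5), 7^(-1 / 2))
  expect_equal(copula_cdf(copula_model("gumbel", 1), 0.3, 0.7), 0.21)
  models <- list(copula_model("clayton", 3), copula_model("clayton", -0.5),
                 copula_model("frank", 5), copula_model("frank", -4),
                 copula_model("gumbel", 2.5))
  set.seed(3)
  for (m in models) {
    expect_equal(copula_cdf(m, 0.42, 1), 0.42, tolerance = 1e-12)
    expect_equal(copula_cdf(m, 1, 0.42), 0.42, tolerance = 1e-12)
    u <- runif(50); v <- runif(50)
    expect_equal(copula_cdf(m, u, v),
                 mapply(oracle_cdf, u = u, v = v,
                        MoreArgs = list(family = m$family, theta = m$theta)),
                 tolerance = 1e-12)
    # 2-increasing on random rectangles
    u1 <- runif(50); u2 <- u1 + runif(50) * (1 - u1)
    v1 <- runif(50); v2 <- v1 + runif(50) * (1 - v1)
    vol <- copula_cdf(m, u2, v2) - copula_cdf(m, u2, v1) -
      copula_cdf(m, u1, v2) + copula_cdf(m, u1, v1)
    expect_true(all(vol >= -1e-12))
  }
  # independence limit of Clayton/Frank as theta -> 0
  u <- runif(20); v <- runif(20)
  expect_equal(copula_cdf(copula_model("clayton", 1e-6), u, v), u * v,
               tolerance = 1e-4)
  expect_equal(copula_cdf(copula_model("frank", 1e-6), u, v), u * v,
               tolerance = 1e-4)
  expect_error(copula_model("clayton", -2), "domain")
  expect_error(copula_cdf(copula_model("frank", 2), 1.2, 0.5), "\\[0, 1\\]")
})

test_that("h-function is the u-derivative of the CDF and is monotone in v", {
  m1 <- copula_model("gumbel", 1)
  v <- seq(0.05, 0.95, by = 0.1)
  expect_equal(conditional_cdf(m1, v, 0.3), v)

  m <- copula_model("clayton", 2)
  grid <- seq(0.01, 0.99, length.out = 100)
  expect_true(all(diff(conditional_cdf(m, grid, 0.4)) >= 0))

  set.seed(4)
  for (fam in c("clayton", "frank", "gumbel")) {
    for (k in 1:20) {
      th <- switch(fam, clayton = runif(1, 0.3, 6),
                   frank = runif(1, -8, 8), gumbel = runif(1, 1.1, 6))
      m <- copula_model(fam, th)
      u <- runif(1, 0.05, 0.95); vv <- runif(1, 0.05, 0.95)
      eps <- 1e-6
      fd <- (copula_cdf(m, u + eps, vv) - copula_cdf(m, u - eps, vv)) /
        (2 * eps)
      expect_lt(abs(fd - conditional_cdf(m, vv, u)), 1e-5)
    }
  }
})

test_that("conditional quantile inverts the h-function for every family", {
  set.seed(5)
  for (fam in c("clayton", "frank", "gumbel")) {
    th <- c(clayton = 4, frank = -6, gumbel = 3)[[fam]]
    m <- copula_model(fam, th)
    p <- runif(30, 0.01, 0.99); u <- runif(30, 0.05, 0.95)
    v <- conditional_quantile(m, p, u)
    expect_lt(max(abs(conditional_cdf(m, v, u) - p)), 1e-7)
  }
  # negative-dependence Clayton goes through the bisection path
  m <- copula_model("clayton", -0.4)
  p <- seq(0.1, 0.9, by = 0.2)
  v <- conditional_quantile(m, p, 0.3)
  expect_lt(max(abs(conditional_cdf(m, v, 0.3) - p)), 1e-7)
})

test_that("conditional sampling is seeded, uniform under independence and centred", {
  m <- copula_model("gumbel", 1)
  s1 <- conditional_sample(m, 0.4, 3000, seed = 11)
  s2 <- conditional_sample(m, 0.4, 3000, seed = 11)
  expect_identical(s1, s2)
  expect_gt(stats::ks.test(s1, "punif")$p.value, 0.01)

  m8 <- copula_model("clayton", 8)
  sm <- conditional_sample(m8, 0.5, 3000, seed = 12)
  med_analytic <- conditional_quantile(m8, 0.5, 0.5)
  expect_lt(abs(median(sm) - med_analytic), 0.05)
})

test_that("ML fitting recovers a known parameter and validates its input", {
  uv <- sample_copula(copula_model("clayton", 2), 2000, seed = 21)
  fit <- fit_copula(rank_transform(uv[, 1]), rank_transform(uv[, 2]),
                    "clayton")
  expect_gt(fit$theta, 1.7)
  expect_lt(fit$theta, 2.3)
  expect_true(is.finite(fit$loglik))
  expect_identical(fit$n, 2000L)
  expect_error(fit_copula(runif(5), runif(5), "frank"), "at least 10")
  expect_error(fit_copula(c(0, runif(19)), runif(20), "frank"), "inside")
})

test_that("goodness-of-fit selection is an argmin over the CvM distances", {
  uv <- sample_copula(copula_model("gumbel", 3), 500, seed = 22)
  g <- select_copula(rank_transform(uv[, 1]), rank_transform(uv[, 2]))
  expect_s3_class(g, "copula_gof")
  sel_dist <- g$table$distance[g$table$family == g$selected$family]
  expect_true(all(sel_dist <= g$table$distance))
  expect_identical(g$selected$family, "gumbel")
  expect_error(select_copula(runif(10), runif(10)), "at least 30")
})

test_that("fitted copula models round-trip through plain-text files", {
  m <- fit_copula(rank_transform(rnorm(100)), rank_transform(rnorm(100)),
                  "frank")
  path <- withr::local_tempfile(fileext = ".txt")
  write_copula_model(m, path)
  back <- read_copula_model(path)
  expect_identical(back$family, m$family)
  expect_equal(back$theta, m$theta, tolerance = 1e-15)
  expect_identical(back$n, m$n)
})
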