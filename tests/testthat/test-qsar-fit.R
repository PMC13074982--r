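# MLR fitting and the validation suite.

test_that("noiseless linear data are recovered exactly", {
  d <- gen_linear(n = 40, beta = c(3, -1, 0.5), beta0 = 2, sigma = 0, seed = 3)
  fit <- fit_mlr(d$x, d$y)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$rmse, 0, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), c(2, 3, -1, 0.5), tolerance = 1e-8)
  expect_equal(q2_loo(fit), 1, tolerance = 1e-8)
})

test_that("a constant response is flagged as degenerate", {
  x <- data.frame(a = rnorm(20), b = rnorm(20))
  fit <- fit_mlr(x, rep(5, 20))
  expect_true(fit$degenerate)
  expect_equal(fit$r_squared, 0)
  expect_true(is.na(fit$f_statistic))
})

test_that("rank-deficient designs raise a singular-design error", {
  d <- gen_linear(n = 30, beta = c(1, 2), sigma = 0, seed = 4)
  x <- d$x
  x$dup <- x$x1
  expect_error(fit_mlr(x, d$y), class = "mpqsar_singular")
})

test_that("coefficients are unbiased within Monte-Carlo error", {
  d <- gen_linear(n = 200, beta = c(3, -1), beta0 = 2, sigma = 1, seed = 11)
  fit <- fit_mlr(d$x, d$y)
  se <- summary(fit$lm)$coefficients[, "Std. Error"]
  expect_true(all(abs(fit$coefficients - c(2, 3, -1)) < 3 * se))
})

test_that("OLS residuals are orthogonal to every design column", {
  for (s in 1:5) {
    d <- gen_linear(n = 50, beta = rnorm(3), sigma = 2, seed = s)
    fit <- fit_mlr(d$x, d$y)
    for (jc in seq_along(d$x))
      expect_lt(abs(sum(fit$residuals * d$x[[jc]])), 1e-8)
    expect_lt(abs(sum(fit$residuals)), 1e-8)
  }
})

test_that("VIF matches per-column regressions and flags collinearity", {
  # columns exactly orthogonal to each other and to the intercept
  q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 3), 40))))[, -1]
  expect_equal(unname(vif(as.data.frame(q))), rep(1, 3), tolerance = 1e-10)

  d <- gen_linear(n = 60, beta = c(1, 1, 1), sigma = 1, seed = 8)
  x <- d$x
  x$x4 <- x$x1 + 0.5 * x$x2 + rnorm(60, 0, 0.4)
  v <- vif(x)
  oracle <- vapply(seq_along(x), function(jc) {
    r2 <- summary(stats::lm(x[[jc]] ~ ., data = x[, -jc, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(v), oracle, tolerance = 1e-8)

  x$dup <- x$x1
  expect_equal(unname(vif(x)[c("x1", "dup")]), c(Inf, Inf))
})

test_that("stepwise selection finds planted signal and stays quiet on noise", {
  with_seed <- mpqsar:::with_seed
  d <- with_seed(21, {
    x <- as.data.frame(matrix(rnorm(100 * 20), 100))
    names(x) <- paste0("d", 1:20)
    list(x = x, y = 5 * x$d7 + rnorm(100))
  })
  sel <- stepwise_select(d$x, d$y)
  expect_true("d7" %in% sel$selected)
  expect_equal(sel$selected[1], "d7")

  null <- with_seed(22, {
    x <- as.data.frame(matrix(rnorm(100 * 20), 100))
    names(x) <- paste0("d", 1:20)
    list(x = x, y = rnorm(100))
  })
  sel0 <- stepwise_select(null$x, null$y)
  expect_lte(length(sel0$selected), 4)   # only chance entries
  expect_true(all(sel0$trace$action %in% c("add", "remove")))

  one <- gen_linear(n = 30, beta = 2, sigma = 0.5, seed = 5)
  expect_equal(stepwise_select(one$x, one$y)$selected, "x1")
})

test_that("the PRESS shortcut equals literal leave-one-out refits", {
  for (s in 1:20) {
    d <- gen_linear(n = 25, beta = rnorm(3), sigma = runif(1, 0.5, 2),
                    seed = s)
    fit <- fit_mlr(d$x, d$y)
    loo <- vapply(seq_len(25), function(i) {
      f <- fit_mlr(d$x[-i, ], d$y[-i])
      stats::predict(f, d$x[i, , drop = FALSE])
    }, numeric(1))
    press <- sum((d$y - loo)^2)
    expect_equal(q2_loo(fit), 1 - press / sum((d$y - mean(d$y))^2),
                 tolerance = 1e-10)
  }
})

test_that("Q2_LOO is non-positive in expectation for pure noise", {
  q2 <- vapply(1:30, function(s) {
    d <- gen_linear(n = 100, beta = rep(0, 4), sigma = 1, seed = 1000 + s)
    q2_loo(fit_mlr(d$x, d$y))
  }, numeric(1))
  expect_lt(mean(q2), 0)
})

test_that("external validation statistics follow their definitions", {
  d <- gen_linear(n = 30, beta = c(2, -1), sigma = 0, seed = 6)
  fit <- fit_mlr(d$x, d$y)
  ext <- q2_ext(fit, d$x, d$y)
  expect_equal(ext$q2_ext, 1)
  expect_equal(ext$r2_ext, 1)
  expect_equal(ext$rmse_v, 0, tolerance = 1e-8)

  # validation rows at the training centroid predict the training mean,
  # so q2_ext is 0 by construction whatever the observed values are
  d2 <- gen_linear(n = 30, beta = c(2, -1), sigma = 1, seed = 7)
  fit2 <- fit_mlr(d2$x, d2$y)
  centroid <- as.data.frame(as.list(colMeans(d2$x)))
  xv <- centroid[rep(1, 5), ]
  yv <- c(-2, 0, 1, 3, 8)
  ext2 <- suppressWarnings(q2_ext(fit2, xv, yv))
  expect_equal(ext2$q2_ext, 0, tolerance = 1e-10)

  # F2 uses the validation mean in the denominator
  ext3 <- q2_ext(fit2, d2$x[1:10, ], d2$y[1:10], variant = "F2")
  pred <- stats::predict(fit2, d2$x[1:10, ])
  expect_equal(ext3$q2_ext,
               1 - sum((pred - d2$y[1:10])^2) /
                   sum((d2$y[1:10] - mean(d2$y[1:10]))^2))
})

test_that("y-randomization is seeded, reproducible and correctly centered", {
  d <- gen_linear(n = 54, beta = c(2, -1, 1, 0.5), sigma = 1, seed = 12)
  fit <- fit_mlr(d$x, d$y)

  # identity permutation reproduces the original fit
  ident <- y_randomize(d$x, d$y, n_perm = 1, perms = list(1:54))
  expect_equal(ident$mean, fit$r_squared, tolerance = 1e-10)

  a <- y_randomize(d$x, d$y, n_perm = 50, seed = 31)
  b <- y_randomize(d$x, d$y, n_perm = 50, seed = 31)
  expect_identical(a$r_squared, b$r_squared)

  # null expectation of R2 is about k / (n - 1)
  big <- y_randomize(d$x, d$y, n_perm = 400, seed = 32)
  expect_lt(abs(big$mean - 4 / 53), 0.025)
})

test_that("95% confidence intervals cover the truth at nominal rate", {
  beta <- c(2, -1, 1, 0.5)
  hits <- 0L; total <- 0L
  for (s in 1:500) {
    d <- gen_linear(n = 54, beta = beta, beta0 = -3, sigma = 2,
                    seed = 5000 + s)
    ci <- stats::confint(fit_mlr(d$x, d$y)$lm)[-1, , drop = FALSE]
    hits <- hits + sum(ci[, 1] <= beta & beta <= ci[, 2])
    total <- total + length(beta)
  }
  expect_gt(hits / total, 0.90)
  expect_lt(hits / total, 1.00)
})

test_that("Q2_LOO never beats R2 on simulated QSAR-sized datasets", {
  for (s in 1:25) {
    d <- gen_linear(n = 54, beta = c(3, -2, 1, 0.5), sigma = 1, seed = 200 + s)
    fit <- fit_mlr(d$x, d$y)
    expect_lte(q2_loo(fit), fit$r_squared)
  }
})
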