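test_that("a single proportional predictor is fit exactly", {
  x <- matrix(seq(2, 20, by = 2), ncol = 1, dimnames = list(NULL, "x"))
  y <- 3 * x[, 1] + 1
  fit <- spi_pls(x, y, ncomp = 1)
  expect_equal(unname(coef(fit, type = "scaled")), 1, tolerance = 1e-12)
  expect_equal(predict(fit, x), y, tolerance = 1e-10)
  m <- r2_rmse(y, fitted(fit))
  expect_equal(m$R2, 1, tolerance = 1e-12)
  expect_equal(m$RMSE, 0, tolerance = 1e-10)
})

test_that("PLS at full rank reproduces the least-squares oracle", {
  for (seed in 1:5) {
    pr <- rand_problem(12, 4, seed)
    fit <- spi_pls(pr$x, pr$y, ncomp = 4)
    expect_equal(unname(coef(fit, type = "scaled")), ols_scaled(pr$x, pr$y),
                 tolerance = 1e-8)
    ols_fitted <- stats::fitted(stats::lm(pr$y ~ pr$x))
    expect_equal(unname(predict(fit, pr$x)), unname(ols_fitted),
                 tolerance = 1e-8)
  }
})

test_that("a response orthogonal to the predictors stops at 0 components", {
  set.seed(21)
  x <- scale(matrix(rnorm(60), 20, 3), scale = FALSE)
  colnames(x) <- paste0("v", 1:3)
  y <- residuals(lm(rnorm(20) ~ x))
  fit <- spi_pls(x, y, ncomp = 2)
  expect_identical(fit$ncomp, 0L)
  expect_equal(predict(fit, x), rep(mean(y), 20), tolerance = 1e-12)
})

test_that("weights are unit norm, scores orthogonal, RMSEcal monotone", {
  for (seed in 1:6) {
    pr <- rand_problem(25, 8, seed)
    a_max <- sample(2:6, 1)
    fit <- spi_pls(pr$x, pr$y, ncomp = a_max)
    expect_equal(colSums(fit$W^2), rep(1, fit$ncomp), tolerance = 1e-10)
    g <- crossprod(fit$scores)
    offdiag <- max(abs(g[upper.tri(g)]))
    expect_lt(offdiag, 1e-8 * sum(diag(g)))
    rmse <- vapply(seq_len(fit$ncomp), function(a)
      r2_rmse(pr$y, predict(fit, pr$x, ncomp = a))$RMSE, numeric(1))
    expect_true(all(diff(rmse) <= 1e-10))
  }
})

test_that("raw coefficients give the same predictions as the scaled path", {
  pr <- rand_problem(30, 6, seed = 31)
  fit <- spi_pls(pr$x, pr$y, ncomp = 3)
  b <- coef(fit, type = "raw")
  xnew <- matrix(rnorm(600, 1, 2), 100, 6,
                 dimnames = list(NULL, colnames(pr$x)))
  raw_path <- b[1] + drop(xnew %*% b[-1])
  expect_equal(predict(fit, xnew), raw_path, tolerance = 1e-8)
})

test_that("shifting the response shifts only the raw intercept", {
  pr <- rand_problem(20, 4, seed = 32)
  f1 <- spi_pls(pr$x, pr$y, ncomp = 2)
  f2 <- spi_pls(pr$x, pr$y + 5, ncomp = 2)
  b1 <- coef(f1); b2 <- coef(f2)
  expect_equal(b2[-1], b1[-1], tolerance = 1e-10)
  expect_equal(unname(b2[1] - b1[1]), 5, tolerance = 1e-10)
})

test_that("permuting predictor columns permutes coefficients and VIP", {
  pr <- rand_problem(25, 5, seed = 33)
  perm <- c(4, 1, 5, 2, 3)
  f1 <- spi_pls(pr$x, pr$y, ncomp = 3)
  f2 <- spi_pls(pr$x[, perm], pr$y, ncomp = 3)
  expect_equal(coef(f2, type = "scaled"),
               coef(f1, type = "scaled")[perm], tolerance = 1e-10)
  expect_equal(vip(f2), vip(f1)[perm], tolerance = 1e-10)
})

test_that("invalid fits are rejected", {
  pr <- rand_problem(10, 3, seed = 34)
  expect_error(spi_pls(pr$x, pr$y, ncomp = 0), "ncomp")
  expect_error(spi_pls(pr$x, pr$y, ncomp = 4), "ncomp")
  expect_error(spi_pls(pr$x, rep(1, 10), ncomp = 1), "constant response")
})

test_that("fit methods are coherent", {
  pr <- rand_problem(20, 4, seed = 35)
  fit <- spi_pls(pr$x, pr$y, ncomp = 2)
  expect_equal(fitted(fit) + residuals(fit), pr$y, tolerance = 1e-12)
  expect_output(print(fit), "PLS1")
  expect_output(print(summary(fit)), "Per-component")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(20L, 3L))
  expect_identical(simulate(fit, 2, seed = 9), simulate(fit, 2, seed = 9))
})
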