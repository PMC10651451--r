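# wrap handmade segment coefficients in the shape pls_cv produces
fake_cv <- function(seg_values, k, reps, var = "v1") {
  p <- 1L
  structure(
    list(seg_coefs = array(seg_values, c(p, 1, k * reps),
                           dimnames = list(var, NULL, NULL)),
         k = k, reps = reps, ncomp_max = 1L, ncomp_best = 1L),
    class = "pls_cv"
  )
}

test_that("the hand-worked 4-segment example is reproduced exactly", {
  cv <- fake_cv(c(1.9, 2.1, 2.0, 2.0), k = 4, reps = 1)
  jk <- jackknife_significance(cv, c(v1 = 2), ncomp = 1)
  expect_equal(jk$se^2, (3 / 4) * (0.01 + 0.01 + 0 + 0), tolerance = 1e-12)
  expect_equal(jk$t, 2 / sqrt(0.015), tolerance = 1e-10)   # ~16.33
  expect_identical(jk$df, 3)
  expect_lt(jk$p_value, 0.001)
  expect_true(jk$ci_lo < 2 && 2 < jk$ci_hi)
})

test_that("perfectly stable coefficients are maximally significant", {
  cv <- fake_cv(rep(0.7, 8), k = 8, reps = 1)
  jk <- jackknife_significance(cv, c(v1 = 0.7), ncomp = 1)
  expect_identical(jk$se, 0)
  expect_identical(jk$p_value, 0)

  jk0 <- jackknife_significance(fake_cv(rep(0, 8), 8, 1), c(v1 = 0), 1)
  expect_identical(jk0$p_value, 1)
})

test_that("p-values of inert variables are approximately uniform", {
  pvals <- c()
  for (seed in 1:20) {
    pr <- rand_problem(60, 10, seed + 900, beta = rep(0, 10), noise_sd = 1)
    cv <- pls_cv(pr$x, pr$y, 3, seed = seed)
    fit <- spi_pls(pr$x, pr$y, ncomp = 3)
    jk <- jackknife_significance(cv, coef(fit, 3, type = "scaled"), 3)
    pvals <- c(pvals, jk$p_value)
  }
  expect_identical(length(pvals), 200L)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
})

test_that("significance of a real effect sharpens with sample size", {
  med_p <- vapply(c(50, 200, 800), function(n) {
    ps <- vapply(1:5, function(seed) {
      pr <- rand_problem(n, 5, seed * 13, beta = c(0.5, rep(0, 4)),
                         noise_sd = 1)
      cv <- pls_cv(pr$x, pr$y, 3, seed = seed)
      fit <- spi_pls(pr$x, pr$y, ncomp = 3)
      jackknife_significance(cv, coef(fit, 3, type = "scaled"), 3)$p_value[1]
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
  expect_lt(med_p[3], 1e-3)
})
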