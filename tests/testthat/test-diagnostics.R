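test_that("closed-form Cook's distance equals the leave-one-out refits", {
  for (seed in 1:5) {
    n <- sample(8:15, 1)
    pr <- rand_problem(n, 3, seed + 70)
    rep_ <- pls_cooks(pr$x, pr$y, ncomp = 2)
    expect_equal(rep_$cooks_d, cooks_brute(pr$x, pr$y, 2), tolerance = 1e-8)
  }
})

test_that("a gross response outlier has the largest distance", {
  x <- matrix(as.numeric(1:8), ncol = 1, dimnames = list(NULL, "x"))
  y <- 2 * x[, 1] + c(0.1, -0.2, 0.1, 0, -0.1, 0.2, -0.1, 0)
  y[4] <- y[4] + 20
  rep_ <- pls_cooks(x, y, ncomp = 1)
  expect_identical(which.max(rep_$cooks_d), 4L)
  expect_equal(rep_$cooks_d, cooks_brute(x, y, 1), tolerance = 1e-8)
})

test_that("duplicating every sample shrinks influence below the 4/n rule", {
  x <- matrix(as.numeric(1:10), ncol = 1, dimnames = list(NULL, "x"))
  y <- 2 * x[, 1] + c(0.12, -0.31, 0.05, 0.22, -0.17,
                      0.08, -0.26, 0.19, -0.04, 0.11)
  orig <- pls_cooks(x, y, ncomp = 1)
  dup <- pls_cooks(rbind(x, x), c(y, y), ncomp = 1)
  expect_true(all(dup$cooks_d[1:10] < orig$cooks_d))
  expect_identical(flag_outliers(dup, "4/n"), character(0))
})

test_that("flag rules select what they promise", {
  rep_ <- structure(
    data.frame(sample_id = c("a", "b", "c", "d", "e", "f"),
               cooks_d = c(0.01, 0.30, 0.02, 0.30, 0.90, 0.005)),
    class = c("spi_outliers", "data.frame")
  )
  expect_identical(flag_outliers(rep_, "top:3"), c("e", "b", "d"))
  expect_identical(flag_outliers(rep_, "1.0"), character(0))
  expect_identical(flag_outliers(rep_, "4/n"), "e")   # threshold 4/6
  low <- rep_; low$cooks_d <- rep(0.01, 6)
  expect_identical(flag_outliers(low, "4/n"), character(0))
  expect_error(flag_outliers(rep_, "bogus"), "unknown")
})

test_that("overfit control reproduces the hand-worked geometry", {
  cal <- data.frame(ncomp = 1:4,
                    R2cal = c(0.2, 0.4, 0.45, 0.46) + c(0.05, 0.06, 0.07, 0.30),
                    RMSEcal = c(1.4, 1.2, 1.1, 1.0))
  cv <- data.frame(ncomp = 1:4, R2cv = c(0.2, 0.4, 0.45, 0.46),
                   RMSEcv = c(1.5, 1.35, 1.3, 1.31))
  ovf <- overfit_report(cal, cv)
  expect_identical(ovf$admissible_ncomp, 1:3)
  # chord from (0.2, 0.05) to (0.46, 0.30): perpendicular distances are
  # 0.131 (A=2) and 0.159 (A=3), so the knee is A=3
  expect_identical(ovf$pareto_ncomp, 3L)
  expect_equal(ovf$table$ratio, cv$RMSEcv / cal$RMSEcal)
})

test_that("dominance and zero-gap edge cases resolve as expected", {
  cal <- data.frame(ncomp = 1:2, R2cal = c(0.5, 0.6), RMSEcal = c(1, 0.9))
  cv <- data.frame(ncomp = 1:2, R2cv = c(0.2, 0.5), RMSEcv = c(1.2, 1.0))
  ovf <- overfit_report(cal, cv)   # A=2 dominates: higher R2cv, lower gap
  expect_identical(ovf$pareto_ncomp, 2L)

  cal0 <- data.frame(ncomp = 1:4, R2cal = c(0.2, 0.4, 0.5, 0.45),
                     RMSEcal = c(1.4, 1.2, 1.1, 1.15))
  cv0 <- data.frame(ncomp = 1:4, R2cv = cal0$R2cal, RMSEcv = cal0$RMSEcal)
  ovf0 <- overfit_report(cal0, cv0)
  expect_identical(ovf0$admissible_ncomp, 1:4)
  expect_identical(ovf0$pareto_ncomp, 3L)  # argmax R2cv at zero gap
})
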