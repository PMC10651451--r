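test_that("the zero-noise single-active limit is an exact affine law", {
  cfg <- synth_config(
    strata = data.frame(label = "ONE", count = 50L),
    stratum_means = c(ONE = 3.5),
    active_set = data.frame(name = "procyanidin_B1", beta = 1),
    noise_sd = 0, outlier_fraction = 0, seed = 4
  )
  g <- generate_wine_dataset(cfg)
  z <- (g$dataset$x[, "procyanidin_B1"] - 5) / 2   # configured mean/SD
  expect_equal(g$dataset$y, 3.5 + z, tolerance = 1e-12)
  expect_equal(g$truth$population_R2, 1)
})

test_that("the default configuration reproduces the study design", {
  g <- generate_wine_dataset(synth_config(seed = 1))
  expect_identical(dim(g$dataset), c(110L, 52L))
  expect_identical(length(unique(g$dataset$stratum)), 12L)
  expect_identical(length(g$truth$outlier_indices), 5L)  # ceiling(5/110 * 110)
  expect_identical(length(g$truth$active), 19L)
  expect_equal(g$truth$population_R2, 0.65, tolerance = 1e-10)
  # 12 positive, 7 negative true signs
  b <- g$truth$true_coefficients[g$truth$active]
  expect_identical(sum(b > 0), 12L)
  expect_identical(sum(b < 0), 7L)

  g2 <- generate_wine_dataset(synth_config(seed = 1))
  expect_identical(g$dataset, g2$dataset)   # byte-identical reproducibility
  g3 <- generate_wine_dataset(synth_config(seed = 2))
  expect_false(identical(g$dataset$y, g3$dataset$y))
})

test_that("an oracle fit on the true actives recovers the target R2", {
  r2 <- vapply(1:50, function(seed) {
    cfg <- synth_config(
      strata = data.frame(label = "BULK", count = 500L),
      stratum_means = c(BULK = 3.8),
      outlier_fraction = 0, seed = seed
    )
    g <- generate_wine_dataset(cfg)
    df <- data.frame(y = g$dataset$y, g$dataset$x[, g$truth$active])
    summary(stats::lm(y ~ ., df))$r.squared
  }, numeric(1))
  expect_lt(abs(median(r2) - 0.65), 0.07)
})

test_that("generated columns hit their configured moments and blocks", {
  cfg <- synth_config(strata = data.frame(label = "BULK", count = 1000L),
                      stratum_means = c(BULK = 3.8),
                      outlier_fraction = 0, seed = 8)
  g <- generate_wine_dataset(cfg)
  x <- g$dataset$x
  se_mean <- 2 / sqrt(1000)
  expect_true(all(abs(colMeans(x) - 5) < 3 * se_mean))
  expect_true(all(abs(apply(x, 2, sd) - 2) < 3 * 2 / sqrt(2 * 999)))

  blocks <- (seq_len(52) - 1) %% 5 + 1
  cors <- cor(x)
  within <- cors[outer(blocks, blocks, "==") & upper.tri(cors)]
  cross <- cors[outer(blocks, blocks, "!=") & upper.tri(cors)]
  expect_gt(mean(within), mean(cross) + 0.2)
})

test_that("outlier injection displaces exactly the promised samples", {
  ds <- strata_dataset(c(A = 50, B = 50), p = 2, seed = 9)
  none <- inject_outliers(ds, 0, 6)
  expect_identical(none$dataset, ds)
  expect_identical(none$indices, integer(0))

  inj <- inject_outliers(ds, 0.05, 6, seed = 2)
  expect_identical(length(inj$indices), 5L)
  moved <- which(inj$dataset$y != ds$y)
  expect_identical(moved, inj$indices)
  expect_equal(abs(inj$dataset$y[moved] - ds$y[moved]),
               rep(6 * sd(ds$y), 5), tolerance = 1e-12)
  expect_identical(ds$y, strata_dataset(c(A = 50, B = 50), p = 2, seed = 9)$y)

  expect_error(inject_outliers(ds, 0.5, 6), "0.5")
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synth_config(strata = data.frame(label = "A", count = 3L),
                            stratum_means = c(A = 3)),
               "exceed n_latent_factors")
  expect_error(synth_config(active_set = data.frame(name = "unobtainium",
                                                    beta = 1)),
               "unobtainium")
  expect_error(synth_config(outlier_fraction = 0.7), "outlier_fraction")
  # a between-stratum spread too large for the noise budget at this R2
  expect_error(
    generate_wine_dataset(synth_config(
      active_set = data.frame(name = "procyanidin_B1", beta = 0.3),
      target_r2 = 0.9, seed = 1
    )),
    "unattainable"
  )
})
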