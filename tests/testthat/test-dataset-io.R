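test_that("wine_dataset validates its pieces", {
  x <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  ds <- wine_dataset(c("s1", "s2", "s3"), c("A", "A", "B"), x, c(1, 2, 3))
  expect_s3_class(ds, "wine_dataset")
  expect_identical(dim(ds), c(3L, 2L))

  expect_error(wine_dataset(c("s1", "s1", "s3"), c("A", "A", "B"), x, 1:3),
               "duplicate")
  expect_error(wine_dataset(c("s1", "s2"), c("A", "A", "B"), x, 1:3),
               "same length")
  expect_error(wine_dataset(c("s1", "s2", "s3"), c("A", "", "B"), x, 1:3),
               "empty stratum")
  xna <- x; xna[1, 1] <- NA
  expect_error(wine_dataset(c("s1", "s2", "s3"), c("A", "A", "B"), xna, 1:3),
               "missing")
})

test_that("CSV round trip preserves the dataset", {
  ds <- strata_dataset(c(A = 4, B = 5), p = 4, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_wine_csv(ds, path)
  back <- read_wine_csv(path)
  expect_identical(back$sample_id, ds$sample_id)
  expect_identical(back$stratum, ds$stratum)
  expect_equal(back$x, ds$x, tolerance = 1e-12)
  expect_equal(back$y, ds$y, tolerance = 1e-12)
})

test_that("malformed CSVs are rejected with informative errors", {
  ds <- strata_dataset(c(A = 4, B = 4), p = 3, seed = 5)
  path <- tempfile(fileext = ".csv")

  df <- as.data.frame(ds)
  df$v2 <- 7   # constant column
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_wine_csv(path), "constant.*v2")

  df <- as.data.frame(ds)[, -2]  # no stratum
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_wine_csv(path), "stratum")

  df <- as.data.frame(ds)[1:2, ]  # too small
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_wine_csv(path), "at least 3")

  df <- as.data.frame(ds)
  df$v1 <- as.character(df$v1)
  df$v1[2] <- "n/a"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_wine_csv(path), "non-numeric.*v1")
})

test_that("sample and predictor subsetting behave like the matrix ops", {
  ds <- strata_dataset(c(A = 5, B = 5), p = 4, seed = 9)
  sub <- subset_samples(ds, ds$stratum == "A")
  expect_identical(length(sub$y), 5L)
  expect_identical(unique(sub$stratum), "A")

  keep <- c("v1", "v3")
  sub2 <- subset_predictors(ds, keep)
  expect_identical(colnames(sub2$x), keep)
  expect_error(subset_predictors(ds, c("v1", "nope")), "nope")
})
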