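test_that("the study design splits 77/33 with the expected stratum counts", {
  ds <- strata_dataset(design_counts(), p = 2, seed = 1)
  sp <- stratified_split(ds, train_frac = 0.7, seed = 1)
  expect_identical(length(sp$train$y), 77L)
  expect_identical(length(sp$test$y), 33L)
  expect_identical(sp$counts$n_test,
                   c(3L, 3L, 2L, 3L, 3L, 1L, 3L, 3L, 3L, 4L, 2L, 3L))
  # removing the five influential training samples leaves 72
  expect_identical(length(sp$train$y) - 5L, 72L)
})

test_that("largest-remainder allocation matches hand enumeration", {
  # 3 strata of 5 at 70%: floors (3,3,3), remainders all .5, total must be
  # round(10.5) = 11, so two strata (first two, stable ties) get an extra
  ds <- strata_dataset(c(A = 5, B = 5, C = 5), seed = 2)
  sp <- stratified_split(ds, 0.7, seed = 2)
  expect_identical(sum(sp$counts$n_train), 11L)
  expect_identical(sp$counts$n_train, c(4L, 4L, 3L))

  # exact halves stay exact
  ds2 <- strata_dataset(c(A = 4, B = 4), seed = 3)
  sp2 <- stratified_split(ds2, 0.5, seed = 3)
  expect_identical(sp2$counts$n_train, c(2L, 2L))
})

test_that("degenerate fractions are rejected", {
  ds <- strata_dataset(c(A = 4, B = 4), seed = 4)
  expect_error(stratified_split(ds, 1), "between 0 and 1")
  expect_error(stratified_split(ds, 0), "between 0 and 1")
})

test_that("splits are deterministic, disjoint and proportional", {
  for (seed in 1:5) {
    set.seed(seed * 100)
    counts <- sample(1:12, sample(3:8, 1), replace = TRUE)
    names(counts) <- paste0("S", seq_along(counts))
    frac <- runif(1, 0.4, 0.85)
    ds <- strata_dataset(counts, seed = seed)
    sp1 <- stratified_split(ds, frac, seed = seed)
    sp2 <- stratified_split(ds, frac, seed = seed)
    expect_identical(sp1$train$sample_id, sp2$train$sample_id)

    joint <- c(sp1$train$sample_id, sp1$test$sample_id)
    expect_setequal(joint, ds$sample_id)
    expect_identical(anyDuplicated(joint), 0L)
    expect_identical(sum(sp1$counts$n_train),
                     as.integer(floor(frac * length(ds$y) + 0.5)))
    expect_true(all(abs(sp1$counts$n_train - frac * counts) <= 1))
  }
})
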