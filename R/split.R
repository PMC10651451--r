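#' Stratified train/test split with largest-remainder allocation
#'
#' Splits a dataset into training and test partitions so that each stratum
#' (grape variety x region) keeps, as closely as possible, its share of the
#' whole: the training quota of stratum s starts at
#' `floor(train_frac * n_s)`, then the remaining seats up to
#' `round(train_frac * n)` are handed out in order of decreasing fractional
#' remainder (largest-remainder rounding, ties by stratum order of first
#' appearance). Which samples fill each stratum's quota is random under
#' `seed`.
#'
#' @param dataset a [wine_dataset].
#' @param train_frac fraction of samples for training, strictly in (0, 1).
#'   Default 0.7.
#' @param seed integer seed for the within-stratum shuffles.
#' @return An object of class `spi_split`: list with `train` and `test`
#'   (`wine_dataset`s) and `counts`, a data.frame with per-stratum
#'   `n`, `n_train`, `n_test`.
#' @export
stratified_split <- function(dataset, train_frac = 0.7, seed = 1L) {
  stopifnot(inherits(dataset, "wine_dataset"))
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be strictly between 0 and 1")
  strata <- unique(dataset$stratum)
  n_s <- vapply(strata, function(s) sum(dataset$stratum == s), integer(1))
  if (any(n_s < 1L)) stop("every stratum must have at least one sample")

  # round-half-up, so e.g. 10.5 target samples allocate 11 to training
  total_train <- floor(train_frac * length(dataset$y) + 0.5)
  quota <- floor(train_frac * n_s)
  remainder <- train_frac * n_s - quota
  extra <- total_train - sum(quota)
  if (extra > 0) {
    # stable sort: ties keep stratum order of first appearance
    winners <- order(remainder, decreasing = TRUE)[seq_len(extra)]
    quota[winners] <- quota[winners] + 1L
  } else if (extra < 0) {
    losers <- order(remainder, decreasing = FALSE)[seq_len(-extra)]
    quota[losers] <- quota[losers] - 1L
  }
  quota <- pmin(pmax(quota, 0L), n_s)

  train_idx <- with_seed(seed, {
    picks <- lapply(seq_along(strata), function(i) {
      members <- which(dataset$stratum == strata[i])
      sample_exact(members, quota[i])
    })
    unlist(picks)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(dataset$y), train_idx)

  counts <- data.frame(
    stratum = strata,
    n = as.integer(n_s),
    n_train = as.integer(quota),
    n_test = as.integer(n_s - quota),
    stringsAsFactors = FALSE
  )
  structure(
    list(train = subset_samples(dataset, train_idx),
         test = subset_samples(dataset, test_idx),
         counts = counts,
         train_frac = train_frac, seed = seed),
    class = "spi_split"
  )
}

#' @export
print.spi_split <- function(x, ...) {
  cat(sprintf("Stratified split (train_frac = %.2f): %d train / %d test\n",
              x$train_frac, length(x$train$y), length(x$test$y)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
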