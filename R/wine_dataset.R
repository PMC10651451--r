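#' Construct a wine dataset
#'
#' A `wine_dataset` bundles the pieces a calibration needs: sample
#' identifiers, a stratum label per sample (grape variety x region of origin),
#' a numeric predictor matrix of physico-chemical parameters, and the Saliva
#' Precipitation Index (SPI) response in g/L gallic-acid equivalent (GAE).
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param stratum character vector of stratum labels, one per sample.
#' @param x numeric matrix (samples x predictors) with column names.
#' @param y numeric response vector (SPI, g/L GAE).
#'
#' @return An object of class `wine_dataset`: a list with elements
#'   `sample_id`, `stratum`, `x`, `y`.
#' @export
wine_dataset <- function(sample_id, stratum, x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  sample_id <- as.character(sample_id)
  stratum <- as.character(stratum)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(sample_id) != n || length(stratum) != n || length(y) != n)
    stop("sample_id, stratum, x rows and y must all have the same length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyNA(x))
    stop("predictor matrix contains missing values")
  if (anyNA(y)) stop("response contains missing values")
  if (any(stratum == "")) stop("empty stratum label")
  structure(
    list(sample_id = sample_id, stratum = stratum, x = x, y = y),
    class = "wine_dataset"
  )
}

#' @export
print.wine_dataset <- function(x, ...) {
  cat("Wine dataset:", nrow(x$x), "samples,", ncol(x$x), "predictors,",
      length(unique(x$stratum)), "strata\n")
  cat("SPI range:", sprintf("%.2f - %.2f g/L GAE\n",
                            min(x$y), max(x$y)))
  tab <- table(x$stratum)
  cat("Strata:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.wine_dataset <- function(x, ...) {
  data.frame(sample_id = x$sample_id, stratum = x$stratum,
             x$x, spi = x$y, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' @export
dim.wine_dataset <- function(x) dim(x$x)

#' Subset a wine dataset by sample index
#'
#' @param dataset a `wine_dataset`.
#' @param i integer or logical index over samples.
#' @return A `wine_dataset` with the selected samples.
#' @export
subset_samples <- function(dataset, i) {
  stopifnot(inherits(dataset, "wine_dataset"))
  wine_dataset(dataset$sample_id[i], dataset$stratum[i],
               dataset$x[i, , drop = FALSE], dataset$y[i])
}

#' Select predictor columns of a wine dataset
#'
#' @param dataset a `wine_dataset`.
#' @param vars character vector of predictor names (or integer index).
#' @return A `wine_dataset` restricted to the chosen predictors.
#' @export
subset_predictors <- function(dataset, vars) {
  stopifnot(inherits(dataset, "wine_dataset"))
  if (is.character(vars)) {
    missing <- setdiff(vars, colnames(dataset$x))
    if (length(missing))
      stop("predictors not in dataset: ", paste(missing, collapse = ", "))
  }
  wine_dataset(dataset$sample_id, dataset$stratum,
               dataset$x[, vars, drop = FALSE], dataset$y)
}

#' Read a wine dataset from CSV
#'
#' Expected layout: a header row, first column `sample_id`, second column
#' `stratum`, then numeric predictor columns, and the SPI response `spi` as
#' the last column. Decimal point '.', comma separator, UTF-8.
#'
#' Predictor columns with missing or non-numeric entries are rejected with a
#' message naming them, as are constant (zero-variance) columns, for which
#' autoscaling is undefined.
#'
#' @param path file path of the CSV.
#' @return A [wine_dataset].
#' @export
read_wine_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "stratum", "spi")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  if (names(df)[length(df)] != "spi")
    stop("'spi' must be the last column")
  if (nrow(df) < 3) stop("need at least 3 samples, got ", nrow(df))
  pred_names <- setdiff(names(df), req)
  if (!length(pred_names)) stop("no predictor columns found")
  xs <- df[pred_names]
  bad <- names(xs)[!vapply(xs, function(col) {
    is.numeric(col) && !anyNA(col)
  }, logical(1))]
  if (length(bad))
    stop("non-numeric or missing values in predictor column(s): ",
         paste(bad, collapse = ", "))
  x <- as.matrix(xs)
  const <- colnames(x)[apply(x, 2, function(col) diff(range(col)) == 0)]
  if (length(const))
    stop("constant predictor column(s): ", paste(const, collapse = ", "))
  wine_dataset(df$sample_id, df$stratum, x, df$spi)
}

#' Write a wine dataset to CSV
#'
#' Inverse of [read_wine_csv()]: `sample_id,stratum,<predictors>,spi`.
#'
#' @param dataset a `wine_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wine_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "wine_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
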