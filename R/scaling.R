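#' Fit an autoscaling (center + unit-variance) transform
#'
#' Column means and standard deviations (n-1 denominator) of the training
#' predictors, plus the response mean and SD. Test data must be transformed
#' with these training statistics only, never refit.
#'
#' @param x numeric training predictor matrix.
#' @param y numeric training response vector.
#' @return An object of class `spi_scaler`: list with `means`, `sds`,
#'   `y_mean`, `y_sd`.
#' @export
fit_scaler <- function(x, y) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples to autoscale")
  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  y_sd <- stats::sd(y)
  if (is.na(y_sd) || y_sd == 0) stop("constant response")
  structure(
    list(means = means, sds = sds, y_mean = mean(y), y_sd = y_sd),
    class = "spi_scaler"
  )
}

#' Apply an autoscaling transform
#'
#' @param scaler an `spi_scaler` from [fit_scaler()].
#' @param x matrix to scale (columns matching the training predictors), or
#'   `NULL`.
#' @param y response vector to scale, or `NULL`.
#' @return The scaled `x`, the scaled `y`, or `list(x = , y = )` when both
#'   are supplied.
#' @export
apply_scaler <- function(scaler, x = NULL, y = NULL) {
  stopifnot(inherits(scaler, "spi_scaler"))
  xs <- if (!is.null(x)) {
    x <- as.matrix(x)
    if (ncol(x) != length(scaler$means)) stop("column count mismatch")
    sweep(sweep(x, 2, scaler$means, "-"), 2, scaler$sds, "/")
  }
  ys <- if (!is.null(y)) (y - scaler$y_mean) / scaler$y_sd
  if (!is.null(x) && !is.null(y)) list(x = xs, y = ys)
  else if (!is.null(x)) xs else ys
}

#' Invert an autoscaling transform
#'
#' @inheritParams apply_scaler
#' @return Data mapped back to original units; same shapes as
#'   [apply_scaler()].
#' @export
invert_scaler <- function(scaler, x = NULL, y = NULL) {
  stopifnot(inherits(scaler, "spi_scaler"))
  xr <- if (!is.null(x)) {
    x <- as.matrix(x)
    sweep(sweep(x, 2, scaler$sds, "*"), 2, scaler$means, "+")
  }
  yr <- if (!is.null(y)) y * scaler$y_sd + scaler$y_mean
  if (!is.null(x) && !is.null(y)) list(x = xr, y = yr)
  else if (!is.null(x)) xr else yr
}
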