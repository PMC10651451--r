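#' Export a fitted SPI model to portable JSON
#'
#' Writes the raw-unit linear form of the calibration — intercept and one
#' coefficient per predictor in measurement units — together with the
#' scaled coefficients, scaling statistics and component count, so the
#' model can be applied elsewhere by direct substitution of unscaled
#' laboratory values.
#'
#' @param model an `spi_pls` fit.
#' @param path output JSON path.
#' @param ncomp component count exported (default: the model's).
#' @param provenance optional named list (seed, configuration hash, ...)
#'   stored verbatim.
#' @return `path`, invisibly.
#' @seealso [load_spi_model()]
#' @export
export_spi_model <- function(model, path, ncomp = model$ncomp,
                             provenance = list()) {
  stopifnot(inherits(model, "spi_pls"))
  b_raw <- coef(model, ncomp = ncomp, type = "raw")
  obj <- list(
    model = "spi_pls",
    response = "SPI (g/L GAE)",
    ncomp = ncomp,
    intercept = unname(b_raw[1]),
    coefficients = as.list(b_raw[-1]),
    coefficients_scaled = as.list(coef(model, ncomp = ncomp,
                                       type = "scaled")),
    scaling = list(means = as.list(model$scaler$means),
                   sds = as.list(model$scaler$sds),
                   y_mean = model$scaler$y_mean,
                   y_sd = model$scaler$y_sd),
    provenance = provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a portable SPI model from JSON
#'
#' Reads either a full export from [export_spi_model()] or a plain
#' coefficient file holding just `intercept` and a `coefficients` map —
#' the minimal portable form of a linear SPI calibration.
#'
#' @param path JSON path.
#' @return An object of class `spi_linear_model`: list with `intercept`,
#'   `coefficients` (named, raw units) and any further fields present in
#'   the file. Supports `predict()` and `coef()`.
#' @export
load_spi_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$intercept) || is.null(obj$coefficients))
    stop("not a portable SPI model: needs 'intercept' and 'coefficients'")
  coefs <- unlist(obj$coefficients)
  structure(
    list(intercept = as.numeric(obj$intercept),
         coefficients = coefs,
         ncomp = obj$ncomp, scaling = obj$scaling,
         provenance = obj$provenance),
    class = "spi_linear_model"
  )
}

#' @export
predict.spi_linear_model <- function(object, newdata, ...) {
  x <- newdata_matrix(newdata, names(object$coefficients))
  drop(object$intercept + x %*% object$coefficients)
}

#' @export
coef.spi_linear_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.spi_linear_model <- function(x, ...) {
  cat("Portable SPI linear model:", length(x$coefficients),
      "variables, intercept", format(x$intercept), "g/L GAE\n")
  invisible(x)
}

#' The packaged 19-variable SPI reference calibration
#'
#' Loads the raw-coefficient SPI model shipped with the package: a
#' 19-variable linear calibration of the Saliva Precipitation Index of red
#' wines (g/L GAE) that can be applied to unscaled laboratory measurements
#' by direct substitution.
#'
#' @return An `spi_linear_model` (see [load_spi_model()]).
#' @examples
#' ref <- spi_reference_model()
#' zero <- setNames(rep(0, 19), names(ref$coefficients))
#' predict(ref, t(as.matrix(zero)))  # the intercept, 2.4385 g/L GAE
#' @export
spi_reference_model <- function() {
  load_spi_model(system.file("extdata", "spi_reference_model.json",
                             package = "spipls", mustWork = TRUE))
}
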