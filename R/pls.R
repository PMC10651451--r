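#' Fit a PLS1 regression (NIPALS) for SPI calibration
#'
#' Fits a univariate-response partial least squares regression by the NIPALS
#' algorithm. Predictors and response are autoscaled (centered, unit SD with
#' the n-1 denominator) internally; the scaling model is stored so that
#' predictions, raw-unit coefficients and the portable intercept are all
#' recoverable.
#'
#' Per component a, on the current deflated `X_a`, `y_a`:
#' \deqn{w_a = X_a' y_a / ||X_a' y_a||, \quad t_a = X_a w_a,}
#' \deqn{p_a = X_a' t_a / (t_a' t_a), \quad q_a = y_a' t_a / (t_a' t_a),}
#' then \eqn{X_{a+1} = X_a - t_a p_a'} and \eqn{y_{a+1} = y_a - q_a t_a}.
#' Scaled-unit coefficients at A components are
#' \eqn{b = W (P'W)^{-1} q}. Extraction stops early when
#' `||X_a' y_a||` falls below `tol` (no covariance left to model); the
#' achieved number of components is recorded in `$ncomp`.
#'
#' @param x numeric predictor matrix (samples x parameters), column names
#'   required for interpretable output.
#' @param y numeric response (SPI, g/L GAE).
#' @param ncomp number of latent components to extract; must lie in
#'   `1..min(n-1, p)`.
#' @param tol early-stop tolerance on `||X'y||` for degenerate components.
#' @return An object of class `spi_pls`: list with weight matrix `W`
#'   (columns unit norm), X-loadings `P`, scores `scores` (orthogonal
#'   columns), y-loadings `q`, achieved `ncomp`, the `scaler`
#'   ([fit_scaler()]), scaled-unit coefficient path `coef_path`
#'   (p x ncomp, column A = coefficients using components 1..A),
#'   training data hooks and fit metrics.
#' @seealso [coef.spi_pls()], [predict.spi_pls()], [vip()], [r2_rmse()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x[, 1] - 0.5 * x[, 2] + rnorm(20, sd = 0.1)
#' fit <- spi_pls(x, y, ncomp = 2)
#' coef(fit)
#' @export
spi_pls <- function(x, y, ncomp, tol = 1e-12) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y dimensions differ")
  if (!is.numeric(ncomp) || length(ncomp) != 1 || ncomp < 1 ||
      ncomp > min(n - 1, p))
    stop("ncomp must lie in 1..min(n-1, p) = 1..", min(n - 1, p))
  ncomp <- as.integer(ncomp)
  scaler <- fit_scaler(x, y)
  sc <- apply_scaler(scaler, x, y)
  core <- nipals_pls1(sc$x, sc$y, ncomp, tol = tol)

  a_fit <- core$ncomp
  coef_path <- matrix(0, p, max(a_fit, 1),
                      dimnames = list(colnames(x), NULL))
  if (a_fit >= 1) {
    for (a in seq_len(a_fit)) {
      Wa <- core$W[, seq_len(a), drop = FALSE]
      Pa <- core$P[, seq_len(a), drop = FALSE]
      coef_path[, a] <- Wa %*% solve(crossprod(Pa, Wa), core$q[seq_len(a)])
    }
  }

  obj <- structure(
    list(W = core$W, P = core$P, scores = core$scores, q = core$q,
         ncomp = a_fit, ncomp_requested = ncomp,
         scaler = scaler, coef_path = coef_path,
         predictor_names = colnames(x),
         x = x, y = y, n = n, p = p, call = match.call()),
    class = "spi_pls"
  )
  obj$fitted_values <- predict(obj, x)
  obj
}

# NIPALS PLS1 core on already-scaled data; returns achieved components
nipals_pls1 <- function(xs, ys, ncomp, tol = 1e-12) {
  n <- nrow(xs); p <- ncol(xs)
  if (all(abs(ys) < .Machine$double.eps)) stop("all-zero response")
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tt <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xa <- xs; ya <- ys
  a_fit <- 0L
  for (a in seq_len(ncomp)) {
    cov <- crossprod(Xa, ya)
    nc <- sqrt(sum(cov^2))
    if (nc < tol) break
    w <- cov / nc
    t <- drop(Xa %*% w)
    tt <- sum(t^2)
    P[, a] <- crossprod(Xa, t) / tt
    q[a] <- sum(ya * t) / tt
    W[, a] <- w
    Tt[, a] <- t
    Xa <- Xa - tcrossprod(t, P[, a])
    ya <- ya - q[a] * t
    a_fit <- a
  }
  list(W = W[, seq_len(a_fit), drop = FALSE],
       P = P[, seq_len(a_fit), drop = FALSE],
       scores = Tt[, seq_len(a_fit), drop = FALSE],
       q = q[seq_len(a_fit)],
       ncomp = a_fit)
}

#' Regression coefficients of an SPI PLS model
#'
#' `type = "scaled"` returns coefficients for autoscaled predictors and
#' response (the units in which VIP and jack-knife significance operate);
#' `type = "raw"` back-transforms to original measurement units,
#' \eqn{b_j^{raw} = b_j^{scaled} \, s_y / s_j}, with portable intercept
#' \eqn{b_0 = \bar y - \sum_j b_j^{raw} \bar x_j}, so SPI can be predicted
#' by direct substitution of unscaled laboratory values.
#'
#' @param object an `spi_pls` fit.
#' @param ncomp number of components to use (default: the model's achieved
#'   components).
#' @param type `"raw"` (with `(Intercept)` first) or `"scaled"`.
#' @param ... unused.
#' @return Named numeric vector of coefficients.
#' @export
coef.spi_pls <- function(object, ncomp = object$ncomp,
                         type = c("raw", "scaled"), ...) {
  type <- match.arg(type)
  b_scaled <- coef_scaled(object, ncomp)
  if (type == "scaled") return(b_scaled)
  sc <- object$scaler
  b_raw <- b_scaled * sc$y_sd / sc$sds
  intercept <- sc$y_mean - sum(b_raw * sc$means)
  c("(Intercept)" = unname(intercept), b_raw)
}

coef_scaled <- function(object, ncomp) {
  if (object$ncomp == 0L)
    return(stats::setNames(numeric(object$p), object$predictor_names))
  if (ncomp < 1 || ncomp > object$ncomp)
    stop("ncomp must lie in 1..", object$ncomp,
         " (achieved components of this fit)")
  stats::setNames(object$coef_path[, ncomp], object$predictor_names)
}

#' Predict SPI for new samples
#'
#' Applies the training autoscaling to `newdata`, multiplies by the
#' scaled-unit coefficients at `ncomp` components, and maps back to g/L GAE.
#' Numerically identical (to rounding) to direct substitution into the
#' raw-coefficient linear equation from [coef.spi_pls()].
#'
#' @param object an `spi_pls` fit.
#' @param newdata matrix or data.frame with the model's predictor columns.
#'   Extra columns are ignored when names are available.
#' @param ncomp number of components to use.
#' @param ... unused.
#' @return Numeric vector of predicted SPI (g/L GAE).
#' @export
predict.spi_pls <- function(object, newdata, ncomp = object$ncomp, ...) {
  x <- newdata_matrix(newdata, object$predictor_names)
  if (object$ncomp == 0L)
    return(rep(object$scaler$y_mean, nrow(x)))
  b <- coef_scaled(object, ncomp)
  xs <- apply_scaler(object$scaler, x = x)
  invert_scaler(object$scaler, y = drop(xs %*% b))
}

newdata_matrix <- function(newdata, predictor_names) {
  if (inherits(newdata, "wine_dataset")) newdata <- newdata$x
  x <- as.matrix(as.data.frame(newdata)[, , drop = FALSE])
  if (!is.null(colnames(x)) && !is.null(predictor_names)) {
    missing <- setdiff(predictor_names, colnames(x))
    if (length(missing))
      stop("newdata lacks predictor column(s): ",
           paste(missing, collapse = ", "))
    x <- x[, predictor_names, drop = FALSE]
  } else if (ncol(x) != length(predictor_names)) {
    stop("newdata has ", ncol(x), " columns; model expects ",
         length(predictor_names))
  }
  storage.mode(x) <- "double"
  x
}

#' @export
fitted.spi_pls <- function(object, ...) object$fitted_values

#' @export
residuals.spi_pls <- function(object, ...) object$y - object$fitted_values

#' @export
print.spi_pls <- function(x, ...) {
  cat("SPI PLS1 regression (NIPALS)\n")
  cat(sprintf("  %d samples, %d predictors, %d component(s)", x$n, x$p,
              x$ncomp))
  if (x$ncomp < x$ncomp_requested)
    cat(sprintf(" (stopped early; %d requested)", x$ncomp_requested))
  cat("\n")
  m <- r2_rmse(x$y, x$fitted_values)
  cat(sprintf("  R2cal = %.3f, RMSEcal = %.3f g/L GAE\n", m$R2, m$RMSE))
  invisible(x)
}

#' @export
summary.spi_pls <- function(object, ...) {
  a_seq <- seq_len(max(object$ncomp, 1))
  tab <- do.call(rbind, lapply(a_seq, function(a) {
    yh <- predict(object, object$x, ncomp = min(a, object$ncomp))
    m <- r2_rmse(object$y, yh)
    data.frame(ncomp = a, R2cal = m$R2, RMSEcal = m$RMSE)
  }))
  structure(list(fit = object, per_component = tab),
            class = "summary.spi_pls")
}

#' @export
print.summary.spi_pls <- function(x, ...) {
  print(x$fit)
  cat("Per-component calibration fit:\n")
  print(x$per_component, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.spi_pls <- function(x, ncomp = x$ncomp, ...) {
  yh <- predict(x, x$x, ncomp = ncomp)
  graphics::plot(x$y, yh, xlab = "Measured SPI (g/L GAE)",
                 ylab = "Predicted SPI (g/L GAE)",
                 main = sprintf("Calibration, %d component(s)", ncomp), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate responses from a fitted SPI PLS model
#'
#' Draws new response vectors as fitted values plus Gaussian noise with the
#' residual standard deviation (df = n - ncomp - 1).
#'
#' @param object an `spi_pls` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data.frame with `nsim` columns, one simulated response each.
#' @export
simulate.spi_pls <- function(object, nsim = 1, seed = NULL, ...) {
  df <- max(object$n - object$ncomp - 1, 1)
  s <- sqrt(sum(residuals(object)^2) / df)
  draw <- function() object$fitted_values + stats::rnorm(object$n, sd = s)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}

#' Variable Importance in Projection (VIP) scores
#'
#' \deqn{VIP_j = \sqrt{p \sum_{a \le A} SSY_a w_{ja}^2 / \sum_{a \le A}
#'   SSY_a}, \quad SSY_a = q_a^2 \, t_a' t_a,}
#' with unit-norm weight columns, so the mean square of the VIP scores is 1
#' by construction. Variables with VIP > 1 contribute more than an average
#' variable to the explained response variance.
#'
#' @param object an `spi_pls` fit.
#' @param ncomp number of components over which importance is accumulated.
#' @return Named numeric vector of VIP scores (length p, all >= 0).
#' @export
vip <- function(object, ncomp = object$ncomp) {
  stopifnot(inherits(object, "spi_pls"))
  if (object$ncomp < 1) stop("model has no components")
  if (ncomp < 1 || ncomp > object$ncomp)
    stop("ncomp exceeds achieved components (", object$ncomp, ")")
  a <- seq_len(ncomp)
  ssy <- object$q[a]^2 * colSums(object$scores[, a, drop = FALSE]^2)
  w2 <- object$W[, a, drop = FALSE]^2
  stats::setNames(
    sqrt(object$p * drop(w2 %*% ssy) / sum(ssy)),
    object$predictor_names
  )
}

#' Coefficient of determination and root-mean-square error
#'
#' `R2 = 1 - SS_res / SS_tot` (SS_tot about the mean of `y_true`; may be
#' negative for models worse than the mean) and
#' `RMSE = sqrt(mean((y_true - y_pred)^2))`, in the units of `y`.
#'
#' @param y_true observed values (non-constant, length >= 2).
#' @param y_pred predicted values, same length.
#' @return List with elements `R2` and `RMSE`.
#' @export
r2_rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least 2 observations")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("R2 undefined for constant y_true")
  res <- y_true - y_pred
  list(R2 = 1 - sum(res^2) / ss_tot,
       RMSE = sqrt(mean(res^2)))
}
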