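# gap threshold for the overfitting control |R2cal - R2cv| <= 20%
OVERFIT_GAP_MAX <- 0.20

#' Cook's distance on the PLS score regression
#'
#' Influence screening for calibration samples. The A-component PLS scores
#' `T` give a well-posed least-squares regression `y ~ [1, T]` even when
#' p > n; the classical Cook's distance of that regression,
#' \deqn{D_i = \frac{e_i^2}{p' s^2} \cdot \frac{h_{ii}}{(1-h_{ii})^2}},
#' with p' = A + 1 parameters, residual variance s^2 and hat values h, is
#' identical to the leave-one-out definition
#' \eqn{D_i = ||\hat y - \hat y_{(i)}||^2 / (p' s^2)}.
#'
#' @param x numeric predictor matrix.
#' @param y numeric response.
#' @param ncomp number of PLS components for the score matrix.
#' @param sample_id optional sample identifiers (default row numbers).
#' @return An object of class `spi_outliers`: data.frame with `sample_id`
#'   and `cooks_d` in input order; attributes record `ncomp`.
#' @export
pls_cooks <- function(x, y, ncomp, sample_id = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n <= ncomp + 1) stop("need n > ncomp + 1 samples")
  if (is.null(sample_id)) sample_id <- as.character(seq_len(n))
  fit <- spi_pls(x, y, ncomp = ncomp)
  scores <- fit$scores
  lmfit <- stats::lm(y ~ scores)
  h <- stats::hatvalues(lmfit)
  if (any(h > 1 - 1e-10))
    stop("leverage-one sample(s): ",
         paste(sample_id[h > 1 - 1e-10], collapse = ", "))
  d <- stats::cooks.distance(lmfit)
  # an (numerically) exact fit has no influential samples
  d[!is.finite(d)] <- 0
  out <- data.frame(sample_id = sample_id, cooks_d = as.numeric(d),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "ncomp") <- fit$ncomp
  class(out) <- c("spi_outliers", "data.frame")
  out
}

#' Flag influential samples from a Cook's distance report
#'
#' Supported rules: `"4/n"` (flag D > 4/n, a common screening convention),
#' `"1.0"` (flag D > 1) and `"top:k"` (the k largest distances, ties broken
#' by sample id). Flagged ids are returned sorted by decreasing distance.
#'
#' @param report an [pls_cooks()] report.
#' @param rule character rule string.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_outliers <- function(report, rule = "4/n") {
  stopifnot(inherits(report, "spi_outliers"))
  d <- report$cooks_d
  n <- length(d)
  if (rule == "4/n") {
    keep <- d > 4 / n
  } else if (rule == "1.0") {
    keep <- d > 1
  } else if (grepl("^top:[0-9]+$", rule)) {
    k <- min(as.integer(sub("^top:", "", rule)), n)
    ord <- order(-d, report$sample_id)
    keep <- logical(n)
    keep[ord[seq_len(k)]] <- TRUE
  } else {
    stop("unknown outlier rule: ", rule)
  }
  ids <- report$sample_id[keep]
  ids[order(-d[keep], ids)]
}

#' Overfitting control report with Pareto knee detection
#'
#' Combines calibration and cross-validation metrics per component count
#' into the two overfitting-control views: the gap `|R2cal - R2cv|`
#' (admissible when at most 20%) and the ratio `RMSEcv / RMSEcal`. The
#' Pareto-optimal component count `pareto_ncomp` is the knee of the point
#' set `(R2cv, gap)`: among the Pareto-efficient points (maximal R2cv,
#' minimal gap), ordered by R2cv, the vertex with the largest perpendicular
#' distance to the chord joining the two extremes; with fewer than three
#' Pareto points, the one with maximal R2cv.
#'
#' @param cal data.frame with columns `ncomp`, `R2cal`, `RMSEcal` (e.g.
#'   `summary(fit)$per_component`).
#' @param cv a [pls_cv()] result (or data.frame with `ncomp`, `R2cv`,
#'   `RMSEcv`).
#' @return An object of class `spi_overfit`: list with `table` (per ncomp:
#'   R2cal, R2cv, gap, RMSEcal, RMSEcv, ratio, admissible),
#'   `admissible_ncomp` (integer vector, gap <= 0.20), `pareto_ncomp` and
#'   `gap_max`.
#' @export
overfit_report <- function(cal, cv) {
  if (inherits(cv, "pls_cv"))
    cv <- data.frame(ncomp = seq_len(cv$ncomp_max),
                     R2cv = cv$R2cv, RMSEcv = cv$RMSEcv)
  a <- intersect(cal$ncomp, cv$ncomp)
  if (!length(a)) stop("no common component counts")
  cal <- cal[match(a, cal$ncomp), ]
  cv <- cv[match(a, cv$ncomp), ]
  gap <- abs(cal$R2cal - cv$R2cv)
  tab <- data.frame(
    ncomp = a, R2cal = cal$R2cal, R2cv = cv$R2cv, gap = gap,
    RMSEcal = cal$RMSEcal, RMSEcv = cv$RMSEcv,
    ratio = cv$RMSEcv / cal$RMSEcal,
    admissible = gap <= OVERFIT_GAP_MAX
  )
  structure(
    list(table = tab,
         admissible_ncomp = tab$ncomp[tab$admissible],
         pareto_ncomp = pareto_knee(tab$R2cv, gap, tab$ncomp),
         gap_max = OVERFIT_GAP_MAX),
    class = "spi_overfit"
  )
}

# knee of the (R2cv, gap) trade-off: Pareto subset, then max perpendicular
# distance to the chord between the Pareto extremes
pareto_knee <- function(r2cv, gap, ncomp) {
  efficient <- vapply(seq_along(r2cv), function(i) {
    dominated <- (r2cv >= r2cv[i] & gap <= gap[i]) &
      (r2cv > r2cv[i] | gap < gap[i])
    !any(dominated)
  }, logical(1))
  idx <- which(efficient)
  idx <- idx[order(r2cv[idx])]
  if (length(idx) < 3)
    return(ncomp[idx[which.max(r2cv[idx])]])
  x <- r2cv[idx]; y <- gap[idx]
  x0 <- x[1]; y0 <- y[1]; x1 <- x[length(x)]; y1 <- y[length(y)]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  dist <- abs((x1 - x0) * (y0 - y) - (x0 - x) * (y1 - y0)) / len
  ncomp[idx[which.max(dist)]]
}

#' @export
print.spi_overfit <- function(x, ...) {
  cat(sprintf("Overfitting control (gap threshold %.0f%%)\n",
              100 * x$gap_max))
  print(x$table, row.names = FALSE, digits = 4)
  cat("Admissible component counts:",
      if (length(x$admissible_ncomp))
        paste(x$admissible_ncomp, collapse = ", ") else "none",
      "\nPareto knee at", x$pareto_ncomp, "component(s)\n")
  invisible(x)
}
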